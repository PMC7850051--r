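## differentiation: pairwise FST per SNP and per window under two
## estimators, multilocus genome-wide FST, outlier SNPs, and recomputation
## excluding a region.
##
## Two estimators are reported side by side:
##  * "classical": FST = (pi_total - pi_within) / pi_total with pi from
##    site_pi on read counts (heterozygosity-based, Popoolation2-style).
##  * "anova": a two-level identity-probability moment estimator. Reads are
##    sampled (with replacement) from the pool's haploid chromosomes, and
##    chromosomes from the population, so the within-pool read-pair identity
##    Q1_reads is corrected to a chromosome-pair identity via the 1/n_hap
##    same-chromosome probability: Q1 = (Q1_reads - 1/n_hap)/(1 - 1/n_hap).
##    FST = (Q1 - Q2)/(1 - Q2); the multilocus value is the ratio of summed
##    numerators over summed denominators, never a mean of per-SNP ratios.

#' Classical heterozygosity-based FST for one site
#'
#' `FST = (pi_total - pi_within) / pi_total` where `pi_within` is the mean
#' of the two pools' [site_pi] and `pi_total` the [site_pi] of the summed
#' count vector. NA when the combined site is monomorphic.
#'
#' @param countsA,countsB A,T,C,G count vectors (or sites x 4 matrices) for
#'   the two pools.
#' @param min_count minimum reads per allele (default 1: inputs are assumed
#'   pre-filtered when scanning).
#' @return numeric vector of per-site FST values.
#' @export
fst_classical <- function(countsA, countsB, min_count = 1L) {
  mA <- if (is.matrix(countsA)) countsA else matrix(as.numeric(countsA), 1L)
  mB <- if (is.matrix(countsB)) countsB else matrix(as.numeric(countsB), 1L)
  pi_a <- site_pi(mA, min_count)
  pi_b <- site_pi(mB, min_count)
  pi_t <- site_pi(mA + mB, min_count)
  fst <- (pi_t - (pi_a + pi_b) / 2) / pi_t
  fst[!is.finite(pi_t) | pi_t == 0] <- NA_real_
  fst
}

#' Pool-size-corrected ANOVA (identity-probability) FST
#'
#' Moment estimator accounting for the two-level sampling of pool-seq:
#' reads from pool chromosomes, chromosomes from the population. Returns
#' per-site values and the multilocus ratio-of-sums.
#'
#' @param countsA,countsB A,T,C,G count vectors or sites x 4 matrices.
#' @param n_hap_a,n_hap_b haploid pool sizes (2 x individuals; default 200
#'   for pools of 100 diploids).
#' @return list with `per_site` (numeric vector, NA where coverage < 2 in
#'   either pool or the denominator vanishes), `multilocus` (scalar), and
#'   the raw `num`/`den` components.
#' @export
fst_anova <- function(countsA, countsB, n_hap_a = 200L, n_hap_b = 200L) {
  mA <- if (is.matrix(countsA)) countsA else matrix(as.numeric(countsA), 1L)
  mB <- if (is.matrix(countsB)) countsB else matrix(as.numeric(countsB), 1L)
  stopifnot(n_hap_a >= 2, n_hap_b >= 2)
  cA <- rowSums(mA); cB <- rowSums(mB)
  q1_reads_a <- rowSums(mA * (mA - 1)) / (cA * (cA - 1))
  q1_reads_b <- rowSums(mB * (mB - 1)) / (cB * (cB - 1))
  q1_a <- (q1_reads_a - 1 / n_hap_a) / (1 - 1 / n_hap_a)
  q1_b <- (q1_reads_b - 1 / n_hap_b) / (1 - 1 / n_hap_b)
  q1 <- (q1_a + q1_b) / 2
  q2 <- rowSums(mA * mB) / (cA * cB)
  num <- q1 - q2
  den <- 1 - q2
  bad <- cA < 2 | cB < 2
  num[bad] <- NA_real_
  den[bad] <- NA_real_
  per_site <- num / den
  per_site[!is.finite(per_site)] <- NA_real_
  ok <- !is.na(num) & !is.na(den)
  multilocus <- if (any(ok)) sum(num[ok]) / sum(den[ok]) else NA_real_
  list(per_site = per_site, multilocus = multilocus, num = num, den = den)
}

#' Pairwise FST scan over a pooled_counts object
#'
#' Subsamples to uniform coverage, restricts to SNPs (>= 2 alleles passing
#' `min_count` in the combined pair), and computes both estimators per SNP
#' plus multilocus summaries for every population pair.
#'
#' @param x a `pooled_counts` object.
#' @param pool_sizes integer vector of diploid pool sizes per population
#'   (default 100 each).
#' @param params a [subsample_params] object.
#' @param clamp_zero when TRUE, negative multilocus summaries are clamped
#'   to 0 ("negative FST values are effectively zero").
#' @return list with `per_snp` (data.table: chrom, pos, pop_pair,
#'   fst_classical, fst_anova) and `summary` (data.table: pop_pair,
#'   multilocus fst_classical, fst_anova, n_snps).
#' @export
fst_scan <- function(x, pool_sizes = rep(100L, n_pops(x)),
                     params = subsample_params(), clamp_zero = FALSE) {
  np <- n_pops(x)
  stopifnot(length(pool_sizes) == np)
  sub <- subsample_sync(x, params)
  pairs <- utils::combn(np, 2L)
  per_snp <- list(); summ <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    ok <- sub[[i]]$status == "ok" & sub[[j]]$status == "ok"
    mA <- apply_min_count(sub[[i]]$counts[ok, , drop = FALSE], params$min_count)
    mB <- apply_min_count(sub[[j]]$counts[ok, , drop = FALSE], params$min_count)
    seg <- rowSums((mA + mB) > 0L) >= 2L
    mA <- mA[seg, , drop = FALSE]; mB <- mB[seg, , drop = FALSE]
    cls <- fst_classical(mA, mB)
    anv <- fst_anova(mA, mB, 2L * pool_sizes[i], 2L * pool_sizes[j])
    pair <- paste0(i, "-", j)
    ## classical multilocus also uses ratio of summed numerators/denominators
    pi_a <- site_pi(mA, 1L); pi_b <- site_pi(mB, 1L)
    pi_t <- site_pi(mA + mB, 1L)
    per_snp[[k]] <- data.table::data.table(
      chrom = x$chrom[ok][seg], pos = x$pos[ok][seg], pop_pair = pair,
      fst_classical = cls, fst_anova = anv$per_site,
      cls_num = pi_t - (pi_a + pi_b) / 2, cls_den = pi_t,
      anova_num = anv$num, anova_den = anv$den)
    summ[[k]] <- multilocus_fst(per_snp[[k]], clamp_zero = clamp_zero)
  }
  list(per_snp = data.table::rbindlist(per_snp),
       summary = data.table::rbindlist(summ))
}

#' Multilocus (ratio-of-sums) FST from per-SNP records
#'
#' @param records per-SNP records from [fst_scan] (single population pair,
#'   or grouped externally).
#' @param clamp_zero clamp negative summaries to 0.
#' @return one-row data.table: pop_pair, fst_classical, fst_anova, n_snps.
#' @export
multilocus_fst <- function(records, clamp_zero = FALSE) {
  r <- data.table::as.data.table(records)
  okc <- is.finite(r$cls_den) & r$cls_den > 0
  oka <- is.finite(r$anova_num) & is.finite(r$anova_den)
  ml <- c(sum(r$cls_num[okc]) / sum(r$cls_den[okc]),
          sum(r$anova_num[oka]) / sum(r$anova_den[oka]))
  if (clamp_zero) ml <- pmax(ml, 0)
  pp <- if ("pop_pair" %in% names(r)) r$pop_pair[1] else NA_character_
  data.table::data.table(pop_pair = pp, fst_classical = ml[1],
                         fst_anova = ml[2], n_snps = nrow(r))
}

#' Top-quantile FST outlier SNPs
#'
#' Returns the SNPs at or above the empirical `1 - q` quantile of the
#' chosen estimator. When all values are equal the full set is returned
#' with a `degenerate` attribute.
#'
#' @param records per-SNP data.table from [fst_scan] (or any table with the
#'   chosen column).
#' @param q tail fraction (default 0.01).
#' @param column which estimator column to rank (default "fst_classical").
#' @return data.table of outlier rows (attribute `cutoff`; attribute
#'   `degenerate` when all values tie).
#' @export
fst_outliers <- function(records, q = 0.01, column = "fst_classical") {
  r <- data.table::as.data.table(records)
  v <- r[[column]]
  keep <- is.finite(v)
  r <- r[keep]; v <- v[keep]
  if (!nrow(r)) return(r)
  cutoff <- stats::quantile(v, 1 - q, names = FALSE, type = 7)
  out <- r[v >= cutoff]
  data.table::setattr(out, "cutoff", cutoff)
  data.table::setattr(out, "degenerate", min(v) == max(v))
  out
}

#' Multilocus FST excluding a genomic region
#'
#' Recomputes the genome-wide pairwise multilocus FST over the complement
#' of `region` from the per-SNP records (so a region containing no SNPs
#' leaves the value exactly unchanged). Errors when the region covers every
#' SNP of some pair.
#'
#' @param records per-SNP records from [fst_scan].
#' @param region `c(start, end)` (1-based inclusive) or a list with
#'   start/end; NULL or an empty region leaves the input unchanged.
#' @param clamp_zero clamp negative summaries to 0.
#' @return summary data.table (pop_pair, fst_classical, fst_anova, n_snps)
#'   computed on the complement.
#' @export
fst_excluding <- function(records, region, clamp_zero = FALSE) {
  r <- data.table::as.data.table(records)
  if (is.list(region) && !is.data.frame(region)) {
    region <- c(region$start, region$end)
  }
  keep <- if (is.null(region) || !length(region)) rep(TRUE, nrow(r))
          else !(r$pos >= region[1] & r$pos <= region[2])
  if (!any(keep)) stop("fst_excluding: region covers all SNPs")
  rs <- r[keep]
  rs[, multilocus_fst(.SD, clamp_zero = clamp_zero)[, !"pop_pair"],
     by = pop_pair]
}
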