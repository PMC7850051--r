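## diversity: coverage subsampling and pi / Watterson's theta / Tajima's D
## per site, per window, and per gene.
##
## All statistics operate on reads subsampled to a uniform target coverage
## (multivariate hypergeometric draw without replacement), mirroring the
## subsample-to-uniform-coverage step of pooled pipelines. Tajima's D uses
## the classic formula with sample size n = target coverage: after
## subsampling, the read sample is a well-defined sample of fixed size. This
## is a deliberate simplification relative to pool-size-corrected variants.

#' Subsampling parameters
#'
#' @param target_coverage uniform coverage every retained site is subsampled
#'   to (default 50).
#' @param max_coverage sites above this raw coverage are excluded as
#'   suspected copy-number artifacts (default 100).
#' @param min_count minimum reads supporting an allele for it to be called
#'   (default 2; suppresses sequencing error).
#' @param min_covered_fraction fraction of window positions that must reach
#'   target coverage for the window to be valid (default 0.6).
#' @param seed optional RNG seed for the hypergeometric draws.
#' @return a `subsample_params` list.
#' @export
subsample_params <- function(target_coverage = 50L, max_coverage = 100L,
                             min_count = 2L, min_covered_fraction = 0.6,
                             seed = NULL) {
  stopifnot(target_coverage > 0, target_coverage <= max_coverage,
            min_count >= 1, min_covered_fraction > 0,
            min_covered_fraction <= 1)
  structure(list(target_coverage = as.integer(target_coverage),
                 max_coverage = as.integer(max_coverage),
                 min_count = as.integer(min_count),
                 min_covered_fraction = min_covered_fraction,
                 seed = seed),
            class = "subsample_params")
}

## Multivariate hypergeometric draw of `target` reads from each row of an
## A,T,C,G count matrix, vectorized with sequential conditional rhyper.
rmvhyper_rows <- function(m, target) {
  n_sites <- nrow(m)
  out <- matrix(0L, n_sites, 4L, dimnames = list(NULL, colnames(m)))
  remaining_pool <- rowSums(m)
  remaining_draw <- rep(as.integer(target), length.out = n_sites)
  for (j in 1:3) {
    x <- as.integer(stats::rhyper(n_sites, m = m[, j],
                                  n = remaining_pool - m[, j],
                                  k = remaining_draw))
    out[, j] <- x
    remaining_pool <- remaining_pool - m[, j]
    remaining_draw <- remaining_draw - x
  }
  out[, 4L] <- remaining_draw
  out
}

#' Subsample one site's counts to uniform coverage
#'
#' Sites with coverage below `target_coverage` are "insufficient"; above
#' `max_coverage`, "excluded"; otherwise `target_coverage` reads are drawn
#' without replacement (multivariate hypergeometric) from the observed
#' counts.
#'
#' @param counts numeric vector of A,T,C,G counts for one population at one
#'   site (N/del already excluded).
#' @param params a [subsample_params] object.
#' @return list with `status` ("ok", "insufficient" or "excluded") and
#'   `counts` (the subsampled A,T,C,G vector when status is "ok", else NULL).
#' @export
subsample_site <- function(counts, params = subsample_params()) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 4L, all(counts >= 0L))
  cov <- sum(counts)
  if (cov < params$target_coverage) {
    return(list(status = "insufficient", counts = NULL))
  }
  if (cov > params$max_coverage) {
    return(list(status = "excluded", counts = NULL))
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  m <- matrix(counts, 1L, dimnames = list(NULL, c("A", "T", "C", "G")))
  sub <- rmvhyper_rows(m, params$target_coverage)
  list(status = "ok", counts = stats::setNames(as.integer(sub[1L, ]),
                                               c("A", "T", "C", "G")))
}

#' Subsample every site of a pooled_counts object, per population
#'
#' @param x a `pooled_counts` object.
#' @param params a [subsample_params] object; `params$seed`, when set, makes
#'   the draws reproducible.
#' @return list with one element per population, each a list of `status`
#'   (factor: ok/insufficient/excluded), `counts` (sites x 4 matrix, zero
#'   rows where not ok), and `raw_coverage`.
#' @export
subsample_sync <- function(x, params = subsample_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  lapply(seq_len(n_pops(x)), function(p) {
    m <- count_matrix(x, p)
    cov <- rowSums(m)
    status <- rep("ok", nrow(m))
    status[cov < params$target_coverage] <- "insufficient"
    status[cov > params$max_coverage] <- "excluded"
    sub <- matrix(0L, nrow(m), 4L, dimnames = list(NULL, colnames(m)))
    ok <- status == "ok"
    if (any(ok)) sub[ok, ] <- rmvhyper_rows(m[ok, , drop = FALSE],
                                            params$target_coverage)
    list(status = status, counts = sub, raw_coverage = cov)
  })
}

## Zero out alleles below min_count; returns the filtered matrix.
apply_min_count <- function(m, min_count) {
  if (min_count > 1L) m[m < min_count] <- 0L
  m
}

#' Per-site nucleotide diversity (average pairwise difference)
#'
#' Computes `(c/(c-1)) * (1 - sum(f_a^2))` on the allele counts after
#' zeroing alleles supported by fewer than `min_count` reads (and
#' recomputing c). This equals the mean pairwise difference among the c
#' sampled reads. Sites with c < 2 after filtering return NA (skipped).
#'
#' @param counts A,T,C,G count vector, or a sites x 4 matrix.
#' @param min_count minimum reads per allele (default 2).
#' @return numeric vector of per-site pi values.
#' @export
site_pi <- function(counts, min_count = 2L) {
  m <- if (is.matrix(counts)) counts else matrix(as.numeric(counts), 1L)
  m <- apply_min_count(m, min_count)
  c_eff <- rowSums(m)
  sumsq <- rowSums(m^2)
  pi <- (c_eff / (c_eff - 1)) * (1 - sumsq / c_eff^2)
  pi[c_eff < 2] <- NA_real_
  pi
}

## Number of alleles passing min_count, per site.
n_alleles <- function(m, min_count) {
  rowSums(apply_min_count(m, min_count) > 0L)
}

#' Tajima's D normalizing constants for sample size n
#'
#' @param n sample size (here: the uniform subsampled coverage).
#' @return list with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d <- function(pi_sum, S, konst) {
  if (S == 0) return(NA_real_)
  denom <- sqrt(konst$e1 * S + konst$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pi_sum - S / konst$a1) / denom
}

#' Windowed diversity statistics for one population
#'
#' Computes per-site pi, Watterson's theta, and Tajima's D over
#' nonoverlapping windows. `pi` and `thetaW` are normalized by the number of
#' covered (successfully subsampled) positions, not the raw window length;
#' `covered_frac` is reported so either convention can be reconstructed.
#'
#' @param sub one population's element from [subsample_sync].
#' @param pos integer positions matching the rows of `sub$counts`.
#' @param chrom chromosome name (single value).
#' @param params a [subsample_params] object.
#' @param window_size window width in bp (default 5000).
#' @param genome_length optional; when given, windows tile
#'   `[1, genome_length]`, otherwise they tile the observed position range.
#' @return data.table with columns chrom, start, end, pi, thetaW, tajD,
#'   snps, covered_frac, valid.
#' @export
window_stats <- function(sub, pos, chrom, params = subsample_params(),
                         window_size = 5000L,
                         genome_length = NULL) {
  konst <- tajima_constants(params$target_coverage)
  L <- if (is.null(genome_length)) max(pos) else genome_length
  starts <- seq(1L, L, by = window_size)
  ok <- sub$status == "ok"
  m <- apply_min_count(sub$counts, params$min_count)
  pi_site <- site_pi(sub$counts, params$min_count)
  seg <- rowSums(m > 0L) >= 2L
  widx <- findInterval(pos, starts)
  res <- data.table::data.table(
    chrom = chrom, start = starts,
    end = pmin(starts + window_size - 1L, L))
  n_cov <- tabulate(widx[ok], nbins = length(starts))
  pi_w <- rep(0, length(starts))
  ok_pi <- ok & !is.na(pi_site)
  if (any(ok_pi)) {
    agg <- tapply(pi_site[ok_pi], widx[ok_pi], sum)
    pi_w[as.integer(names(agg))] <- as.numeric(agg)
  }
  S_w <- tabulate(widx[ok & seg], nbins = length(starts))
  res[, `:=`(
    pi = ifelse(n_cov > 0, pi_w / n_cov, 0),
    thetaW = ifelse(n_cov > 0, S_w / (konst$a1 * n_cov), 0),
    tajD = mapply(tajima_d, pi_w, S_w, MoreArgs = list(konst = konst)),
    snps = S_w,
    covered_frac = n_cov / (res$end - res$start + 1L))]
  res[, valid := covered_frac >= params$min_covered_fraction]
  res[]
}

#' Windowed diversity for every population of a pooled_counts object
#'
#' @param x a `pooled_counts` object (single chromosome).
#' @param params a [subsample_params] object.
#' @param window_size window width in bp.
#' @param genome_length optional genome length for window tiling.
#' @return data.table of per-window stats with a `population` column.
#' @export
diversity_scan <- function(x, params = subsample_params(),
                           window_size = 5000L, genome_length = NULL) {
  stopifnot(length(unique(x$chrom)) <= 1L)
  sub <- subsample_sync(x, params)
  out <- lapply(seq_along(sub), function(p) {
    w <- window_stats(sub[[p]], x$pos, x$chrom[1], params, window_size,
                      genome_length)
    w[, population := p]
    w
  })
  data.table::rbindlist(out)
}

#' Gene-wise nucleotide diversity
#'
#' Recomputes pi over the covered CDS positions of a gene model. A gene is
#' `usable` only when its mean raw read coverage exceeds `min_cov`
#' (convention: only genes with coverage > 50 enter reports).
#'
#' @param sub one population's element from [subsample_sync].
#' @param pos positions matching `sub$counts` rows.
#' @param gene a [gene_model].
#' @param params a [subsample_params] object.
#' @param min_cov minimum mean raw coverage for the gene to be usable.
#' @return one-row data.table: gene_id, pi, n_snps, mean_coverage, usable.
#' @export
gene_pi <- function(sub, pos, gene, params = subsample_params(),
                    min_cov = 50) {
  iv <- gene$cds_intervals
  in_cds <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(iv))) {
    in_cds <- in_cds | (pos >= iv[k, 1L] & pos <= iv[k, 2L])
  }
  ok <- in_cds & sub$status == "ok"
  mean_cov <- if (any(in_cds)) mean(sub$raw_coverage[in_cds]) else 0
  n_cov <- sum(ok)
  if (n_cov == 0L) {
    return(data.table::data.table(gene_id = gene$gene_id, pi = NA_real_,
                                  n_snps = 0L, mean_coverage = mean_cov,
                                  usable = FALSE))
  }
  m <- sub$counts[ok, , drop = FALSE]
  pi_vals <- site_pi(m, params$min_count)
  S <- sum(n_alleles(m, params$min_count) >= 2L)
  data.table::data.table(
    gene_id = gene$gene_id,
    pi = sum(pi_vals, na.rm = TRUE) / n_cov,
    n_snps = as.integer(S),
    mean_coverage = mean_cov,
    usable = mean_cov > min_cov)
}

#' Gene-wise pi for all genes and populations
#'
#' @param x a `pooled_counts` object.
#' @param genes list of [gene_model] objects.
#' @param params a [subsample_params] object.
#' @param min_cov usability threshold on mean raw coverage.
#' @return data.table with one row per gene x population.
#' @export
gene_pi_scan <- function(x, genes, params = subsample_params(),
                         min_cov = 50) {
  sub <- subsample_sync(x, params)
  out <- lapply(seq_along(sub), function(p) {
    dt <- data.table::rbindlist(lapply(genes, function(g) {
      gene_pi(sub[[p]], x$pos, g, params, min_cov)
    }))
    dt[, population := p]
    dt
  })
  data.table::rbindlist(out)
}
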