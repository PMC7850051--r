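## sweep_scan: delineate low-diversity regions, bootstrap CIs and
## distribution tails of Tajima's D, and cross-population intersection.

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values numeric vector (finite, non-empty).
#' @param reps bootstrap replicates (default 10000).
#' @param level confidence level (default 0.90).
#' @param seed optional RNG seed.
#' @return named numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(values, reps = 10000L, level = 0.90, seed = NULL) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("bootstrap_ci: empty input")
  if (!all(is.finite(values))) stop("bootstrap_ci: non-finite values")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  ## chunked to keep memory flat at large reps * n
  means <- numeric(reps)
  chunk <- max(1L, min(reps, floor(5e6 / n)))
  done <- 0L
  while (done < reps) {
    k <- min(chunk, reps - done)
    idx <- sample.int(n, n * k, replace = TRUE)
    means[(done + 1L):(done + k)] <-
      colMeans(matrix(values[idx], nrow = n, ncol = k))
    done <- done + k
  }
  alpha <- (1 - level) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(ci_low = q[1], ci_high = q[2])
}

#' Tajima's D distribution summary and tail windows
#'
#' Computes the genome-wide mean with its bootstrap CI and the empirical
#' lower/upper `q` quantile cutoffs (type-7 interpolation). Windows at
#' exactly the cutoff are included in the tail.
#'
#' @param windows data.table of window stats (needs `tajD`; rows with NA or
#'   `valid == FALSE` are ignored).
#' @param q tail fraction (default 0.01 for the top/bottom 1%).
#' @param reps,level,seed passed to [bootstrap_ci].
#' @return list with `summary` (genome_mean, ci_low, ci_high,
#'   lower_tail_cutoff, upper_tail_cutoff, degenerate flag), `lower_tail`
#'   and `upper_tail` (window subsets).
#' @export
tajima_tails <- function(windows, q = 0.01, reps = 10000L, level = 0.90,
                         seed = NULL) {
  w <- data.table::as.data.table(windows)
  if ("valid" %in% names(w)) w <- w[valid == TRUE]
  w <- w[is.finite(tajD)]
  if (nrow(w) == 0L) stop("tajima_tails: no valid Tajima's D values")
  if (nrow(w) < 100L) {
    warning("tajima_tails: fewer than 100 valid windows; quantiles are noisy")
  }
  d <- w$tajD
  ci <- bootstrap_ci(d, reps = reps, level = level, seed = seed)
  lo <- stats::quantile(d, q, names = FALSE, type = 7)
  hi <- stats::quantile(d, 1 - q, names = FALSE, type = 7)
  list(summary = list(genome_mean = mean(d), ci_low = ci[["ci_low"]],
                      ci_high = ci[["ci_high"]], lower_tail_cutoff = lo,
                      upper_tail_cutoff = hi, degenerate = lo == hi),
       lower_tail = w[tajD <= lo],
       upper_tail = w[tajD >= hi])
}

#' Delineate candidate sweep regions from window statistics
#'
#' Finds maximal runs of consecutive valid windows with `pi <
#' pi_threshold`, allowing up to `max_gap_windows` interior windows at or
#' above the threshold. Each region reports the flanking contrast: the mean
#' pi of up to 10 valid windows on each side.
#'
#' @param windows data.table of one population's window stats, sorted by
#'   coordinate (columns chrom, start, end, pi, valid). Invalid windows are
#'   ignored.
#' @param pi_threshold delineation threshold on window pi (default 0.002,
#'   the shading convention used for sweep-region tables).
#' @param max_gap_windows tolerated interior above-threshold windows
#'   (default 1).
#' @return data.table of regions: chrom, start, end, n_windows, min_pi,
#'   mean_pi, flank_pi.
#' @export
delineate_sweeps <- function(windows, pi_threshold = 0.002,
                             max_gap_windows = 1L) {
  w <- data.table::as.data.table(windows)
  if ("valid" %in% names(w)) w <- w[valid == TRUE]
  data.table::setorder(w, start)
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_windows = integer(),
                                  min_pi = numeric(), mean_pi = numeric(),
                                  flank_pi = numeric())
  if (nrow(w) == 0L) return(empty)
  low <- w$pi < pi_threshold
  idx <- which(low)
  if (!length(idx)) return(empty)
  ## group consecutive low windows, merging runs separated by at most
  ## max_gap_windows consecutive (valid) above-threshold windows
  grp <- cumsum(c(1L, diff(idx) > max_gap_windows + 1L))
  regions <- lapply(split(idx, grp), function(ix) {
    lo <- min(ix); hi <- max(ix)
    flank <- c(if (lo > 1L) w$pi[max(1L, lo - 10L):(lo - 1L)],
               if (hi < nrow(w)) w$pi[(hi + 1L):min(nrow(w), hi + 10L)])
    data.table::data.table(
      chrom = w$chrom[lo], start = w$start[lo], end = w$end[hi],
      n_windows = hi - lo + 1L,
      min_pi = min(w$pi[lo:hi]), mean_pi = mean(w$pi[lo:hi]),
      flank_pi = if (length(flank)) mean(flank) else NA_real_)
  })
  data.table::rbindlist(regions)
}

#' Intersect sweep regions across populations
#'
#' The shared core is the coordinate intersection present in all
#' populations; each population's extension is its difference from the
#' core. With an empty intersection the core is absent and the
#' per-population regions are reported individually as extensions.
#'
#' @param regions named list (one element per population) of `c(start,
#'   end)` vectors or single-region data.tables on the same chromosome.
#' @return list with `core` (c(start, end) or NULL) and `extensions`
#'   (named list of two-column matrices of residual intervals per
#'   population; empty matrix when none).
#' @export
intersect_regions <- function(regions) {
  iv <- lapply(regions, function(r) {
    if (is.data.frame(r)) {
      if (nrow(r) == 0L) return(NULL)
      c(min(r$start), max(r$end))
    } else if (is.null(r) || !length(r)) NULL else c(r[1], r[2])
  })
  if (is.null(names(iv))) names(iv) <- paste0("pop", seq_along(iv))
  present <- !vapply(iv, is.null, TRUE)
  core <- NULL
  if (all(present) && length(iv)) {
    lo <- max(vapply(iv, `[`, 0, 1L))
    hi <- min(vapply(iv, `[`, 0, 2L))
    if (lo <= hi) core <- c(start = lo, end = hi)
  }
  extensions <- lapply(iv, function(r) {
    if (is.null(r)) return(matrix(numeric(), 0L, 2L,
                                  dimnames = list(NULL, c("start", "end"))))
    if (is.null(core)) {
      return(matrix(r, 1L, 2L, dimnames = list(NULL, c("start", "end"))))
    }
    out <- NULL
    if (r[1] < core[["start"]]) out <- rbind(out, c(r[1], core[["start"]] - 1))
    if (r[2] > core[["end"]]) out <- rbind(out, c(core[["end"]] + 1, r[2]))
    if (is.null(out)) out <- matrix(numeric(), 0L, 2L)
    dimnames(out) <- list(NULL, c("start", "end"))
    out
  })
  list(core = core, extensions = extensions)
}

#' Full sweep scan over per-population window statistics
#'
#' Delineates sweeps per population, annotates contained genes, and
#' intersects the largest region of each population into a shared core plus
#' per-population extensions.
#'
#' @param windows data.table of window stats with a `population` column
#'   (from [diversity_scan]).
#' @param genes optional list of [gene_model] objects for containment
#'   annotation.
#' @param pi_threshold,max_gap_windows passed to [delineate_sweeps].
#' @return list with `regions` (per-population data.table), `intersection`
#'   (from [intersect_regions]).
#' @export
sweep_scan <- function(windows, genes = NULL, pi_threshold = 0.002,
                       max_gap_windows = 1L) {
  w <- data.table::as.data.table(windows)
  pops <- sort(unique(w$population))
  per_pop <- lapply(pops, function(p) {
    r <- delineate_sweeps(w[population == p], pi_threshold, max_gap_windows)
    if (nrow(r)) r[, population := p]
    r
  })
  names(per_pop) <- paste0("pop", pops)
  regions <- data.table::rbindlist(per_pop, fill = TRUE)
  if (nrow(regions) && !is.null(genes)) {
    regions[, genes := vapply(seq_len(.N), function(i) {
      ids <- vapply(genes, function(g) {
        span <- range(g$cds_intervals)
        if (span[1] >= start[i] && span[2] <= end[i]) g$gene_id else NA_character_
      }, "")
      paste(ids[!is.na(ids)], collapse = ",")
    }, "")]
  }
  ## intersect the largest region per population
  largest <- lapply(per_pop, function(r) {
    if (nrow(r) == 0L) return(NULL)
    r[which.max(n_windows)]
  })
  list(regions = regions, intersection = intersect_regions(largest))
}
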