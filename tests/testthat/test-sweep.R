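test_that("bootstrap_ci: degenerate, width, determinism, errors", {
  # degenerate distribution
  expect_equal(unname(bootstrap_ci(rep(0.3, 20), reps = 500, seed = 1)),
               c(0.3, 0.3))
  # Bernoulli(0.5), n = 1000: width ~ 2 * 1.645 * sqrt(0.25/1000) = 0.052
  set.seed(4)
  v <- rbinom(1000, 1, 0.5)
  ci <- bootstrap_ci(v, reps = 5000, level = 0.90, seed = 2)
  width <- ci[["ci_high"]] - ci[["ci_low"]]
  expect_lt(abs(width - 0.052), 0.011)
  # deterministic under seed
  expect_identical(bootstrap_ci(v, reps = 1000, seed = 9),
                   bootstrap_ci(v, reps = 1000, seed = 9))
  expect_error(bootstrap_ci(numeric()), "empty")
  expect_error(bootstrap_ci(c(1, Inf)), "non-finite")
})

test_that("bootstrap_ci covers the true mean at roughly nominal level", {
  set.seed(15)
  hits <- replicate(500, {
    v <- rnorm(50)
    ci <- bootstrap_ci(v, reps = 2000, level = 0.90)
    ci[["ci_low"]] <= 0 && 0 <= ci[["ci_high"]]
  })
  expect_gte(mean(hits), 0.85)
})

test_that("tajima_tails: quantile cutoffs, ties, degenerate input", {
  w <- data.table::data.table(chrom = "s", start = seq(1, 5000 * 200, 5000),
                              end = seq(5000, 5000 * 200, 5000),
                              tajD = as.numeric(1:200), valid = TRUE)
  tt <- tajima_tails(w, q = 0.01, reps = 200, seed = 1)
  # type-7 interpolated 1% quantile of 1..200 is 2.99; tail = {1, 2}
  expect_equal(tt$summary$lower_tail_cutoff, 2.99)
  expect_equal(sort(tt$lower_tail$tajD), c(1, 2))
  expect_equal(tt$summary$upper_tail_cutoff, 198.01)
  expect_equal(sort(tt$upper_tail$tajD), c(199, 200))
  expect_false(tt$summary$degenerate)
  expect_true(tt$summary$ci_low <= tt$summary$genome_mean)
  expect_true(tt$summary$genome_mean <= tt$summary$ci_high)

  # 100 distinct values: lower tail is the single minimum
  t100 <- tajima_tails(w[1:100], reps = 200, seed = 1)
  expect_equal(t100$lower_tail$tajD, 1)
  # below 100 valid windows: warning, quantiles still computed
  expect_warning(t99 <- tajima_tails(w[1:99], reps = 200, seed = 1),
                 "fewer than 100")
  expect_equal(t99$lower_tail$tajD, 1)

  # all equal: cutoffs coincide, everything is in both tails, flagged
  weq <- data.table::copy(w)[, tajD := 0.5]
  teq <- tajima_tails(weq, reps = 200, seed = 1)
  expect_true(teq$summary$degenerate)
  expect_equal(nrow(teq$lower_tail), 200L)
  expect_equal(nrow(teq$upper_tail), 200L)
})

test_that("delineate_sweeps finds runs with gap tolerance", {
  mk <- function(pi) data.table::data.table(
    chrom = "s", start = seq(1, by = 5000, length.out = length(pi)),
    end = seq(5000, by = 5000, length.out = length(pi)), pi = pi,
    valid = TRUE)
  # single run across windows 2-4 (15 kb)
  r <- delineate_sweeps(mk(c(0.02, 0.0001, 0, 0.0002, 0.02)))
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 5001L)
  expect_equal(r$end, 20000L)
  expect_equal(r$n_windows, 3L)
  expect_equal(r$min_pi, 0)
  # all above threshold: empty
  expect_equal(nrow(delineate_sweeps(mk(rep(0.02, 5)))), 0L)
  # gap tolerance: one interior high window merged at max_gap_windows = 1
  r1 <- delineate_sweeps(mk(c(0.0001, 0.003, 0.0001)), max_gap_windows = 1)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_windows, 3L)
  r0 <- delineate_sweeps(mk(c(0.0001, 0.003, 0.0001)), max_gap_windows = 0)
  expect_equal(nrow(r0), 2L)
  # flanking contrast is the mean pi of up to 10 windows each side
  pi <- c(rep(0.03, 12), rep(0.0001, 3), rep(0.01, 12))
  rf <- delineate_sweeps(mk(pi))
  expect_equal(rf$flank_pi, mean(c(rep(0.03, 10), rep(0.01, 10))))
})

test_that("intersect_regions computes core and extensions", {
  # shared core with one population's extension
  r <- intersect_regions(list(A = c(100, 300), B = c(100, 300),
                              C = c(100, 400)))
  expect_equal(unname(r$core), c(100, 300))
  expect_equal(nrow(r$extensions$A), 0L)
  expect_equal(unname(r$extensions$C[1, ]), c(301, 400))
  # disjoint: no core, regions reported individually
  r2 <- intersect_regions(list(A = c(1, 10), B = c(20, 30)))
  expect_null(r2$core)
  expect_equal(unname(r2$extensions$B[1, ]), c(20, 30))
  # identical regions: empty extensions
  r3 <- intersect_regions(list(A = c(5, 9), B = c(5, 9)))
  expect_equal(unname(r3$core), c(5, 9))
  expect_true(all(vapply(r3$extensions, nrow, 0L) == 0L))
})

test_that("sweep recovery: core and extension within one window", {
  sim <- simulate_pools(sweep_world(seed = 101L))
  params <- subsample_params(seed = 5)
  w <- diversity_scan(sim$sync, params, 5000L, 300000L)
  res <- sweep_scan(w, sim$genes)
  core_true <- sim$truth$sweep_core
  ext_true <- sim$truth$sweep_extension
  # per-population delineation within +/- 1 window (5 kb)
  for (p in 1:3) {
    reg <- res$regions[population == p][which.max(n_windows)]
    end_true <- if (p == 3) ext_true[["end"]] else core_true[2]
    expect_lte(abs(reg$start - core_true[1]), 5000)
    expect_lte(abs(reg$end - end_true), 5000)
  }
  # intersection: shared core + resistant-only extension
  core <- res$intersection$core
  expect_lte(abs(core[["start"]] - core_true[1]), 5000)
  expect_lte(abs(core[["end"]] - core_true[2]), 5000)
  ext3 <- res$intersection$extensions$pop3
  expect_equal(nrow(ext3), 1L)
  expect_lte(abs(ext3[1, "end"] - ext_true[["end"]]), 5000)
  # susceptible populations have no extension
  expect_equal(nrow(res$intersection$extensions$pop1), 0L)
  # the sweep genes are contained in every population's region
  expect_match(res$regions[population == 1]$genes, "para_like")

  # Tajima's D inside the sweep: residual singleton-like variants push D
  # strongly negative, so (a) the genome-wide bottom-1% tail windows all
  # lie inside the sweep, and (b) mean sweep D falls below the bottom-1%
  # cutoff of the neutral background windows. (When the sweep occupies
  # more than 1% of windows the all-window cutoff lands inside the
  # sweep's own distribution, so (b) is asserted against the background.)
  cfg <- sweep_world(seed = 55L, genome = 800000L)
  cfg$diversity_reduction <- 0.05
  cfg <- poolsweep:::validate_sim_config(cfg)
  sim2 <- simulate_pools(cfg)
  p1 <- subsample_params(min_count = 1, seed = 6)
  w2 <- diversity_scan(sim2$sync, p1, 5000L, 800000L)
  w2p <- w2[population == 1]
  in_sweep <- w2p$start >= core_true[1] & w2p$end <= core_true[2]
  tail_all <- tajima_tails(w2p, q = 0.01, reps = 1000, seed = 3)
  expect_true(all(tail_all$lower_tail$start >= core_true[1] &
                    tail_all$lower_tail$end <= core_true[2]))
  tt_bg <- tajima_tails(w2p[!in_sweep], q = 0.01, reps = 1000, seed = 3)
  sweep_d <- w2p[in_sweep & is.finite(tajD)]$tajD
  expect_lt(mean(sweep_d), tt_bg$summary$lower_tail_cutoff)
})
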