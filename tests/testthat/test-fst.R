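test_that("fst_classical matches the stated formulas", {
  # identical pools: by the stated formulas the value is slightly negative
  # because the c/(c-1) correction differs between c = 50 and c = 100;
  # negative values are effectively zero
  ident <- fst_classical(c(30, 20, 0, 0), c(30, 20, 0, 0))
  expect_lte(ident, 0)
  expect_lt(abs(ident), 0.02)
  expect_equal(max(0, ident), 0)
  # fixed difference: FST = 1 exactly
  expect_equal(fst_classical(c(50, 0, 0, 0), c(0, 50, 0, 0)), 1)
  # hand computation through the stated formulas, cross-checked against the
  # brute-force pairwise oracle
  a <- c(30, 20, 0, 0); b <- c(10, 40, 0, 0)
  expect_equal(fst_classical(a, b), 0.158163, tolerance = 1e-5)
  pi_w <- (pairwise_pi_oracle(a) + pairwise_pi_oracle(b)) / 2
  pi_t <- pairwise_pi_oracle(a + b)
  expect_equal(fst_classical(a, b), (pi_t - pi_w) / pi_t, tolerance = 1e-12)
  # monomorphic combined site: NA
  expect_true(is.na(fst_classical(c(50, 0, 0, 0), c(50, 0, 0, 0))))
})

test_that("fst_anova: null expectation, parameter recovery, degeneracy", {
  set.seed(31)
  # identical pools: multilocus estimate near 0 over 1e4 sites
  s0 <- sim_island_counts(1e4, 0)
  expect_lt(abs(fst_anova(s0$A, s0$B)$multilocus), 0.005)
  # island-model FST = 0.10: recovery within +/- 0.01
  s1 <- sim_island_counts(1e4, 0.10)
  expect_lt(abs(fst_anova(s1$A, s1$B)$multilocus - 0.10), 0.01)
  # single read per pool: NA
  expect_true(is.na(fst_anova(c(1, 0, 0, 0), c(0, 1, 0, 0))$per_site))
})

test_that("multilocus ratio-of-sums is invariant to SNP ordering", {
  set.seed(8)
  s <- sim_island_counts(2000, 0.1)
  r1 <- fst_anova(s$A, s$B)$multilocus
  perm <- sample(nrow(s$A))
  r2 <- fst_anova(s$A[perm, ], s$B[perm, ])$multilocus
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("deep sampling: both estimators reach their closed-form limits", {
  # With two demes the heterozygosity-based classical estimator converges
  # to (F/2)/(1 - F/2) (pi_total over two demes captures only half the
  # between-deme variance), while the ANOVA estimator is consistent for F.
  # The persistent offset between the two is why both are reported side by
  # side rather than treated as interchangeable.
  set.seed(12)
  F_true <- 0.1
  deep <- sim_island_counts(20000, F_true, n_hap = 2000L, cov = 500L)
  f <- fst_scan_pair_sized(deep$A, deep$B, 2000L)
  expect_lt(abs(f$anova - F_true), 0.01)
  cls_limit <- (F_true / 2) / (1 - F_true / 2)
  expect_lt(abs(f$classical - cls_limit), 0.01)
})

test_that("fst_outliers ranks the tail and flags degeneracy", {
  r <- data.table::data.table(chrom = "s", pos = 1:100, pop_pair = "1-2",
                              fst_classical = runif(100))
  out <- fst_outliers(r, q = 0.01)
  expect_equal(nrow(out), 1L)
  expect_equal(out$fst_classical, max(r$fst_classical))
  # all equal: all returned, flagged degenerate
  r2 <- data.table::copy(r)[, fst_classical := 0.2]
  out2 <- fst_outliers(r2, q = 0.01)
  expect_equal(nrow(out2), 100L)
  expect_true(attr(out2, "degenerate"))
})

test_that("planted outliers among neutral SNPs are recovered in the top 1%", {
  # no sweep, so the only differentiated sites are the planted ones
  ol_pos <- as.integer(seq(5000, 100000, length.out = 20))
  ol <- data.table::data.table(pos = ol_pos, freq_pop1 = 0.05,
                               freq_pop2 = 0.05, freq_pop3 = 0.95)
  cfg <- sim_config(genome_length = 200000L, sweep_core = NULL,
                    sweep_extension = NULL, fixed_snp = NULL,
                    outlier_snps = ol, seed = 61L)
  sim <- simulate_pools(cfg)
  f <- fst_scan(sim$sync, params = subsample_params(seed = 4))
  out <- fst_outliers(f$per_snp[pop_pair == "1-3"], q = 0.01)
  expect_gte(sum(ol_pos %in% out$pos), 18L)
})

test_that("fst_excluding recomputes over the complement", {
  set.seed(3)
  sim <- simulate_pools(sweep_world(seed = 41L))
  f <- fst_scan(sim$sync, params = subsample_params(seed = 4))
  full <- f$summary[pop_pair == "1-3"]
  # a region containing no SNPs leaves the value exactly unchanged
  gap_region <- c(1L, 2L)   # two bp; no SNP there with this seed
  stopifnot(!any(f$per_snp$pos <= 2))
  same <- fst_excluding(f$per_snp, gap_region)[pop_pair == "1-3"]
  expect_equal(same$fst_classical, full$fst_classical, tolerance = 1e-12)
  # empty region: identical
  same2 <- fst_excluding(f$per_snp, NULL)[pop_pair == "1-3"]
  expect_equal(same2$fst_anova, full$fst_anova, tolerance = 1e-12)
  # removing the sweep (the only strongly differentiated stretch) moves the
  # 1-3 estimate toward the 1-2 (undifferentiated) level
  core <- sim$truth$sweep_core
  ext <- sim$truth$sweep_extension
  no_sweep <- fst_excluding(f$per_snp,
                            c(core[1], ext[["end"]]))[pop_pair == "1-3"]
  expect_lt(no_sweep$fst_classical, full$fst_classical)
  # removing everything errors
  expect_error(fst_excluding(f$per_snp, c(1L, 300000L)), "all SNPs")
})
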