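test_that("subsample_site honours thresholds and the hypergeometric draw", {
  p <- subsample_params(seed = NULL)
  # coverage below target
  expect_equal(subsample_site(c(30, 0, 0, 0), p)$status, "insufficient")
  # coverage above max (copy-number suspicion)
  expect_equal(subsample_site(c(150, 0, 0, 0), p)$status, "excluded")
  # exact-coverage draw totals the target
  set.seed(1)
  s <- subsample_site(c(60, 40, 0, 0), p)
  expect_equal(s$status, "ok")
  expect_equal(sum(s$counts), 50L)
  # hypergeometric mean: E[A] = 50 * 60/100 = 30
  draws <- replicate(2000, subsample_site(c(60, 40, 0, 0), p)$counts["A"])
  se <- sqrt(50 * 0.6 * 0.4 * 50 / 99 / 2000)
  expect_lt(abs(mean(draws) - 30), 3 * se)
  # deterministic under seed
  p7 <- subsample_params(seed = 7)
  expect_identical(subsample_site(c(60, 40, 0, 0), p7),
                   subsample_site(c(60, 40, 0, 0), p7))
})

test_that("subsample preserves totals and proportions (chi-squared GOF)", {
  set.seed(22)
  m <- matrix(rep(c(60L, 30L, 10L, 0L), each = 1e4), ncol = 4)
  sub <- poolsweep:::rmvhyper_rows(m, 50L)
  expect_true(all(rowSums(sub) == 50L))
  # marginal of the A column is Hypergeometric(60, 40, 50)
  k <- 10:50
  p_exp <- dhyper(k, 60, 40, 50)
  obs <- tabulate(sub[, 1] + 1L, nbins = 51L)[k + 1L]
  keep <- p_exp > 1e-6
  gof <- suppressWarnings(
    chisq.test(obs[keep], p = p_exp[keep] / sum(p_exp[keep])))
  expect_gt(gof$p.value, 0.001)
})

test_that("site_pi matches hand-computed values and min_count filtering", {
  # 25/25 split at c = 50: 625/1225 by direct pair counting
  expect_equal(site_pi(c(25, 0, 25, 0), min_count = 2), 625 / 1225,
               tolerance = 1e-12)
  expect_equal(site_pi(c(25, 0, 25, 0)), 0.510204, tolerance = 1e-6)
  # monomorphic
  expect_equal(site_pi(c(50, 0, 0, 0)), 0)
  # rare allele below min_count is zeroed -> site monomorphic
  expect_equal(site_pi(c(49, 0, 0, 1), min_count = 2), 0)
  expect_gt(site_pi(c(49, 0, 0, 1), min_count = 1), 0)
  # c < 2 after filtering: NA (site skipped)
  expect_true(is.na(site_pi(c(1, 0, 0, 0), min_count = 1)))
})

test_that("site_pi equals the brute-force pairwise oracle exhaustively", {
  # all count vectors with coverage <= 20 (4 alleles)
  for (cc in 2:20) {
    parts <- t(as.matrix(expand.grid(a = 0:cc, b = 0:cc, c = 0:cc)))
    parts <- parts[, colSums(parts) <= cc, drop = FALSE]
    m <- t(rbind(parts, cc - colSums(parts)))
    got <- site_pi(m, min_count = 1)
    want <- apply(m, 1, pairwise_pi_oracle)
    expect_equal(got, want, tolerance = 1e-12,
                 label = sprintf("site_pi at coverage %d", cc))
  }
})

test_that("window_stats computes pi, thetaW and Tajima's D per window", {
  k <- tajima_constants(50)
  # a1 at c = 50 by direct summation
  expect_equal(k$a1, sum(1 / seq_len(49)), tolerance = 1e-12)
  expect_equal(k$a1, 4.479205, tolerance = 1e-6)

  params <- subsample_params(min_count = 2, min_covered_fraction = 0.6)
  # build a fully covered 100-site "window": all sites at coverage 50
  n_sites <- 100L
  counts <- matrix(0L, n_sites, 4L,
                   dimnames = list(NULL, c("A", "T", "C", "G")))
  counts[, 1] <- 50L
  sub <- list(status = rep("ok", n_sites), counts = counts,
              raw_coverage = rep(50, n_sites))
  w0 <- window_stats(sub, seq_len(n_sites), "s", params,
                     window_size = 100L, genome_length = 100L)
  # zero SNPs: pi = thetaW = 0, tajD undefined
  expect_equal(w0$pi, 0)
  expect_equal(w0$thetaW, 0)
  expect_true(is.na(w0$tajD))
  expect_equal(w0$covered_frac, 1)
  expect_true(w0$valid)

  # add SNPs; verify against hand-computed sums
  counts[1:5, ] <- 0L
  counts[1:5, 1] <- 25L; counts[1:5, 3] <- 25L
  sub$counts <- counts
  w1 <- window_stats(sub, seq_len(n_sites), "s", params,
                     window_size = 100L, genome_length = 100L)
  pi_sum <- 5 * 625 / 1225
  S <- 5
  expect_equal(w1$pi, pi_sum / 100)
  expect_equal(w1$thetaW, S / (k$a1 * 100))
  expect_equal(w1$snps, 5L)
  D_exp <- (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  expect_equal(w1$tajD, D_exp, tolerance = 1e-12)

  # a window where pi_sum == S/a1 has D exactly 0
  expect_equal(poolsweep:::tajima_d(S / k$a1, S, k), 0)

  # low covered fraction invalidates the window
  sub$status[1:50] <- "insufficient"
  w2 <- window_stats(sub, seq_len(n_sites), "s", params,
                     window_size = 100L, genome_length = 100L)
  expect_false(w2$valid)
  expect_equal(w2$covered_frac, 0.5)
})

test_that("gene_pi restricts to CDS, flags usability, merges exons", {
  params <- subsample_params(min_count = 2)
  n <- 60L
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, c("A", "T", "C", "G")))
  counts[, 1] <- 50L
  counts[10, ] <- c(25L, 25L, 0L, 0L)   # SNP inside first exon
  sub <- list(status = rep("ok", n), counts = counts,
              raw_coverage = rep(80, n))
  one <- gene_model("g_one", "s", "+", cbind(1L, 60L))
  two <- gene_model("g_two", "s", "+", cbind(c(1L, 31L), c(30L, 60L)))
  g1 <- gene_pi(sub, 1:60, one, params)
  g2 <- gene_pi(sub, 1:60, two, params)
  # two-exon gene identical to the concatenated single-exon gene
  expect_equal(g1$pi, g2$pi)
  expect_equal(g1$n_snps, 1L)
  expect_true(g1$usable)

  # no SNPs in CDS: pi exactly 0
  counts[10, ] <- c(50L, 0L, 0L, 0L)
  sub$counts <- counts
  expect_equal(gene_pi(sub, 1:60, one, params)$pi, 0)

  # mean coverage 40 < 50: usable = FALSE
  sub$raw_coverage <- rep(40, n)
  expect_false(gene_pi(sub, 1:60, one, params)$usable)
  # zero covered positions: unusable
  sub$status <- rep("insufficient", n)
  expect_false(gene_pi(sub, 1:60, one, params)$usable)
})

test_that("neutral simulated data give mean Tajima's D within 3 SE of 0", {
  # neutral world: no sweep, no outliers, no error, no drift perturbation;
  # min_count = 1 because on error-free data the rare-allele filter would
  # strip true singletons and bias D upward
  cfg <- sim_config(genome_length = 1000000L, sweep_core = NULL,
                    sweep_extension = NULL, fixed_snp = NULL,
                    error_rate = 0, drift_concentration = Inf, seed = 11L)
  sim <- simulate_pools(cfg)
  params <- subsample_params(min_count = 1, seed = 3)
  sub <- subsample_sync(sim$sync, params)
  w <- window_stats(sub[[1]], sim$sync$pos, cfg$chrom, params, 5000L,
                    cfg$genome_length)
  d <- w[valid == TRUE & is.finite(tajD)]$tajD
  expect_gte(length(d), 200L)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se)
})

test_that("windowed pi inside an eps = 0 sweep is exactly zero", {
  sim <- simulate_pools(sweep_world(seed = 19L))
  params <- subsample_params(seed = 2)
  w <- diversity_scan(sim$sync, params, 5000L, 300000L)
  core <- sim$truth$sweep_core
  inside <- w[start >= core[1] & end <= core[2]]
  expect_true(all(inside$pi == 0))
})
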