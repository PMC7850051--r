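# Shared fixture builders. Everything is generated in code; no binary data.

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# A tiny canonical sync file: 2 populations, 3 sites.
tiny_sync_lines <- function() {
  c("scaf1\t79\tA\t25:25:0:0:0:0\t50:0:0:0:0:0",
    "scaf1\t80\tG\t0:0:0:60:0:0\t0:0:10:40:0:0",
    "scaf1\t81\tT\t0:50:0:0:0:0\t0:50:0:0:1:2")
}

# Minimal GFF3: one plus-strand single-CDS gene, one two-exon gene.
tiny_gff_lines <- function() {
  c("##gff-version 3",
    "scaf1\ttest\tgene\t101\t160\t.\t+\t.\tID=gene_g1",
    "scaf1\ttest\tmRNA\t101\t160\t.\t+\t.\tID=g1;Parent=gene_g1;Name=alpha",
    "scaf1\ttest\tCDS\t101\t160\t.\t+\t0\tParent=g1",
    "scaf1\ttest\tgene\t101\t230\t.\t-\t.\tID=gene_g2",
    "scaf1\ttest\tmRNA\t101\t230\t.\t-\t.\tID=g2;Parent=gene_g2;Name=beta",
    "scaf1\ttest\tCDS\t101\t130\t.\t-\t0\tParent=g2",
    "scaf1\ttest\tCDS\t201\t230\t.\t-\t0\tParent=g2")
}

# Island-model pooled counts for the FST tests: two pools of 100 diploids,
# per-population frequencies Beta-distributed with moments matching a true
# FST, read counts binomial at the pool fraction.
sim_island_counts <- function(m, fst, n_hap = 200L, cov = 50L) {
  p0 <- runif(m, 0.1, 0.9)
  draw <- function() {
    p <- if (fst == 0) p0 else {
      rbeta(m, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
    }
    k <- rbinom(m, n_hap, p)
    alt <- rbinom(m, cov, k / n_hap)
    cbind(A = alt, T = cov - alt, C = 0L, G = 0L)
  }
  list(A = draw(), B = draw())
}

# Structured null for the PCA scan: pools on a 2-D ancestry gradient that
# every SNP drifts along (the regime the chi-squared calibration assumes);
# optional outliers get a fixed group-difference shift on component 1 (a
# two-group axis is then used for that component).
sim_struct_freq <- function(n_pools, m, cov = 50L, tau = 0.06,
                            n_out = 0L, shift = 0.4) {
  ax1 <- if (n_out > 0) rep(c(-1, 1), length.out = n_pools) else
    rnorm(n_pools)
  S <- cbind(ax1, rnorm(n_pools))
  B <- matrix(rnorm(m * 2, 0, tau), m, 2)
  if (n_out > 0) B[seq_len(n_out), 1] <- shift / 2
  p0 <- runif(m, 0.2, 0.8)
  P <- pmin(pmax(p0 + tcrossprod(B, S), 0.01), 0.99)
  list(freq = matrix(rbinom(m * n_pools, cov, P), m, n_pools) / cov,
       out_idx = seq_len(n_out))
}

# Small complete-sweep world reused by the sweep and acceptance tests.
sweep_world <- function(seed = 101L, genome = 300000L) {
  sim_config(genome_length = genome,
             sweep_core = c(100001L, 200000L),                 # 20 windows
             sweep_extension = list(start = 200001L, end = 250000L,
                                    population = 3L),          # 10 windows
             fixed_snp = list(position = 150000L, freq = rep(1, 3)),
             diversity_reduction = 0, error_rate = 0, seed = seed)
}

# Brute-force average pairwise difference among reads: the independent
# oracle for site_pi.
pairwise_pi_oracle <- function(counts) {
  reads <- rep(seq_along(counts), counts)
  n <- length(reads)
  if (n < 2) return(NA_real_)
  diff <- 0L
  for (i in seq_len(n - 1)) {
    diff <- diff + sum(reads[(i + 1):n] != reads[i])
  }
  diff / choose(n, 2)
}

# Multilocus classical + ANOVA FST for a pair of raw count matrices.
fst_scan_pair_sized <- function(mA, mB, n_hap = 200L) {
  pi_a <- site_pi(mA, 1); pi_b <- site_pi(mB, 1); pi_t <- site_pi(mA + mB, 1)
  ok <- is.finite(pi_t) & pi_t > 0
  list(classical = sum(pi_t[ok] - (pi_a[ok] + pi_b[ok]) / 2) / sum(pi_t[ok]),
       anova = fst_anova(mA, mB, n_hap, n_hap)$multilocus)
}
fst_scan_pair <- fst_scan_pair_sized
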