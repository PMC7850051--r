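## synthetic_data: seeded generator of pooled allele-count data (sync +
## GFF3 + FASTA + truth tables) with the statistical structure the sweep
## analysis assumes: neutral-SFS background diversity, a shared hard sweep
## with a population-specific extension, a fixed nonsynonymous "kdr-like"
## SNP, and differentiated flanking outlier SNPs.
##
## The source study is empirical and states no generative model; every
## distributional choice here (Beta drift, Poisson depth, binomial read
## sampling, singleton-like residual variants inside sweeps) is a stand-in,
## chosen once and documented in the methods vignette.

#' Simulation configuration
#'
#' Defaults state the emulated design: 3 populations, pools of 100 diploid
#' individuals (200 chromosomes), 1-Mb genome, 5-kb windows, per-site
#' polymorphism probability theta = 0.10 (calibrated so expected per-site
#' pi matches the ~0.0175 genome-wide diversity of the susceptible
#' populations), raw depth 82x (the study's raw coverage; subsampling
#' targets 50x), sequencing error 1e-3, a 100-kb shared sweep core with a
#' 100-kb resistant-only extension, a fixed nonsynonymous SNP inside a
#' sweep-core gene, and 20 differentiated flanking SNPs.
#'
#' @param n_populations number of pooled populations.
#' @param pool_individuals diploid individuals per pool (haploid 2n).
#' @param genome_length genome size in bp.
#' @param window window width in bp (used for tiling conventions).
#' @param theta per-site probability that a site is polymorphic.
#' @param depth_mean mean sequencing depth (Poisson lambda).
#' @param error_rate per-base miscall probability, in \[0, 0.1\].
#' @param drift_concentration Beta concentration for per-population drift
#'   around the ancestral frequency (FST between replicate pools is
#'   approximately 1/(1 + concentration)).
#' @param sweep_core c(start, end) of the shared low-diversity region.
#' @param sweep_extension list(start, end, population) for the
#'   resistant-only extension.
#' @param diversity_reduction epsilon in \[0,1\]: fraction of polymorphic
#'   sites surviving inside sweep regions (0 = complete sweep).
#' @param residual_singleton when TRUE, surviving sweep-region variants are
#'   redrawn as singleton-like recent mutations (derived copies 1-2 of 2n),
#'   which is what drives Tajima's D strongly negative inside sweeps.
#' @param fixed_snp list(position, freq) — the kdr-like SNP; freq is the
#'   per-population alternate frequency (default 1 everywhere). Its codon
#'   context (CTT, Leu) is written into the FASTA so the screen labels the
#'   L->F change.
#' @param outlier_snps data.frame(pos, freq_pop1..freq_popK) of
#'   differentiated SNPs; NULL uses 20 defaults flanking the sweep.
#' @param chrom scaffold name for all outputs.
#' @param seed RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_populations = 3L, pool_individuals = 100L,
                       genome_length = 1000000L, window = 5000L,
                       theta = 0.10, depth_mean = 82, error_rate = 0.001,
                       drift_concentration = 200,
                       sweep_core = c(400001L, 500000L),
                       sweep_extension = list(start = 500001L,
                                              end = 600000L,
                                              population = 3L),
                       diversity_reduction = 0,
                       residual_singleton = TRUE,
                       fixed_snp = list(position = 450000L,
                                        freq = rep(1, n_populations)),
                       outlier_snps = NULL,
                       chrom = "scaf_sim_1", seed = 1L) {
  cfg <- list(n_populations = as.integer(n_populations),
              pool_individuals = as.integer(pool_individuals),
              genome_length = as.integer(genome_length),
              window = as.integer(window), theta = theta,
              depth_mean = depth_mean, error_rate = error_rate,
              drift_concentration = drift_concentration,
              sweep_core = if (!is.null(sweep_core)) as.integer(sweep_core),
              sweep_extension = sweep_extension,
              diversity_reduction = diversity_reduction,
              residual_singleton = isTRUE(residual_singleton),
              fixed_snp = fixed_snp, outlier_snps = outlier_snps,
              chrom = chrom, seed = as.integer(seed))
  if (is.null(cfg$outlier_snps)) cfg$outlier_snps <- default_outliers(cfg)
  validate_sim_config(cfg)
}

default_outliers <- function(cfg) {
  if (is.null(cfg$sweep_core) || is.null(cfg$sweep_extension)) {
    out <- data.table::data.table(pos = integer())
    for (p in seq_len(cfg$n_populations)) {
      data.table::set(out, j = paste0("freq_pop", p), value = numeric())
    }
    return(out)
  }
  pos <- c(seq(cfg$sweep_core[1] - 10000L, cfg$sweep_core[1] - 1000L,
               by = 1000L),
           seq(cfg$sweep_extension$end + 1000L,
               cfg$sweep_extension$end + 10000L, by = 1000L))
  f <- matrix(0.05, length(pos), cfg$n_populations)
  f[, cfg$sweep_extension$population] <- 0.95
  out <- data.table::data.table(pos = as.integer(pos))
  for (p in seq_len(cfg$n_populations)) {
    data.table::set(out, j = paste0("freq_pop", p), value = f[, p])
  }
  out
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_populations >= 1, cfg$pool_individuals >= 1,
            cfg$genome_length >= cfg$window,
            cfg$theta >= 0, cfg$theta <= 1, cfg$depth_mean > 0,
            cfg$error_rate >= 0, cfg$error_rate <= 0.1,
            cfg$diversity_reduction >= 0, cfg$diversity_reduction <= 1,
            cfg$drift_concentration > 0)
  chk_region <- function(r) {
    stopifnot(r[1] >= 1, r[2] <= cfg$genome_length, r[1] <= r[2])
  }
  if (!is.null(cfg$sweep_core)) chk_region(cfg$sweep_core)
  ext <- cfg$sweep_extension
  if (!is.null(ext)) {
    chk_region(c(ext$start, ext$end))
    stopifnot(ext$population >= 1, ext$population <= cfg$n_populations)
  }
  fs <- cfg$fixed_snp
  if (!is.null(fs)) {
    stopifnot(fs$position >= 1, fs$position + 2 <= cfg$genome_length,
              length(fs$freq) == cfg$n_populations,
              all(fs$freq >= 0), all(fs$freq <= 1))
  }
  ol <- cfg$outlier_snps
  if (!is.null(ol) && nrow(ol)) {
    fcols <- paste0("freq_pop", seq_len(cfg$n_populations))
    stopifnot(all(fcols %in% names(ol)),
              all(ol$pos >= 1), all(ol$pos <= cfg$genome_length),
              !anyDuplicated(ol$pos))
    for (j in fcols) stopifnot(all(ol[[j]] >= 0), all(ol[[j]] <= 1))
  }
  structure(cfg, class = "sim_config")
}

#' Draw derived-allele counts from the neutral site frequency spectrum
#'
#' Under the standard neutral model the probability of derived-allele
#' count i among 2N chromosomes is proportional to 1/i, i in
#' \[1, 2N - 1\].
#'
#' @param two_n number of chromosomes (>= 2).
#' @param size number of draws.
#' @return integer vector of derived counts.
#' @export
neutral_sfs_count <- function(two_n, size = 1L) {
  if (two_n < 2) stop("neutral_sfs_count: two_n must be >= 2")
  i <- seq_len(two_n - 1L)
  sample(i, size, replace = TRUE, prob = 1 / i)
}

#' Probability mass of the neutral SFS
#' @param two_n number of chromosomes.
#' @return numeric vector: P(i) for i = 1..2N-1 (proportional to 1/i).
#' @export
neutral_sfs_pmf <- function(two_n) {
  i <- seq_len(two_n - 1L)
  (1 / i) / sum(1 / i)
}

## Apply uniform miscalls: each read switches to one of the other three
## bases with probability e. m is sites x 4.
apply_seq_error <- function(m, e) {
  if (e == 0) return(m)
  n <- nrow(m)
  err <- matrix(0L, n, 4L)
  for (b in 1:4) err[, b] <- stats::rbinom(n, m[, b], e)
  m <- m - err
  for (b in 1:4) {
    others <- setdiff(1:4, b)
    x1 <- stats::rbinom(n, err[, b], 1 / 3)
    x2 <- stats::rbinom(n, err[, b] - x1, 1 / 2)
    m[, others[1]] <- m[, others[1]] + x1
    m[, others[2]] <- m[, others[2]] + x2
    m[, others[3]] <- m[, others[3]] + (err[, b] - x1 - x2)
  }
  m
}

#' Simulate pooled sequencing data
#'
#' Generates the full synthetic dataset: a reference FASTA, gene models
#' (GFF3), per-site pooled read counts in sync layout for every position of
#' the genome, and a truth table. Deterministic under `config$seed`; the
#' same seed yields byte-identical output files.
#'
#' @param config a [sim_config].
#' @param out_dir optional directory; when given, writes `sim.sync`,
#'   `sim.gff3`, `sim.fasta`, `truth_snps.tsv` and `truth_regions.tsv`
#'   through the io module and returns the paths in the result.
#' @return list with `sync` (a `pooled_counts` object), `fasta`, `genes`,
#'   `truth` (list: sweep_core, sweep_extension, snps table, poly_pos),
#'   `config`, and `paths` when `out_dir` was given.
#' @export
simulate_pools <- function(config = sim_config(), out_dir = NULL) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  L <- cfg$genome_length
  np <- cfg$n_populations
  two_n <- 2L * cfg$pool_individuals
  genome <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  ## gene models (all inside the default coordinate layout, scaled with
  ## the sweep core); the kdr-like gene hosts the fixed SNP at codon
  ## position 1 with reference codon CTT (Leu)
  genes <- sim_genes(cfg)
  fs <- cfg$fixed_snp
  if (!is.null(fs)) {
    genome[fs$position] <- "C"
    genome[fs$position + 1L] <- "T"
    genome[fs$position + 2L] <- "T"
  }

  ## background polymorphic sites from the neutral SFS
  special_pos <- c(if (!is.null(fs)) fs$position, cfg$outlier_snps$pos)
  is_poly <- stats::runif(L) < cfg$theta
  is_poly[special_pos] <- FALSE
  core <- cfg$sweep_core
  ext <- cfg$sweep_extension
  in_core <- function(pos) {
    if (is.null(core)) rep(FALSE, length(pos))
    else pos >= core[1] & pos <= core[2]
  }
  in_ext <- function(pos) {
    if (is.null(ext)) rep(FALSE, length(pos))
    else pos >= ext$start & pos <= ext$end
  }
  ## sweep core: polymorphism thinned to a fraction epsilon in all pops
  eps <- cfg$diversity_reduction
  poly_pos <- which(is_poly)
  core_sites <- in_core(poly_pos)
  drop <- core_sites & stats::runif(length(poly_pos)) >= eps
  poly_pos <- poly_pos[!drop]
  core_sites <- in_core(poly_pos)
  n_poly <- length(poly_pos)

  anc_count <- neutral_sfs_count(two_n, n_poly)
  anc_freq <- anc_count / two_n
  nu <- cfg$drift_concentration
  freq <- matrix(0, n_poly, np)
  for (p in seq_len(np)) {
    ## drift_concentration = Inf: no perturbation (replicate samples of one
    ## panmictic population; the world Tajima's D is calibrated against)
    freq[, p] <- if (is.infinite(nu)) anc_freq else
      stats::rbeta(n_poly, nu * anc_freq, nu * (1 - anc_freq))
  }
  if (cfg$residual_singleton && any(core_sites)) {
    ## survivors inside the core are recent post-sweep mutations
    k <- sum(core_sites)
    for (p in seq_len(np)) {
      freq[core_sites, p] <- sample(1:2, k, TRUE, prob = c(0.8, 0.2)) / two_n
    }
  }
  ## extension: only the designated population is swept
  ext_sites <- in_ext(poly_pos)
  if (any(ext_sites)) {
    pe <- ext$population
    k <- sum(ext_sites)
    surv <- stats::runif(k) < eps
    fnew <- numeric(k)
    if (cfg$residual_singleton) {
      fnew[surv] <- sample(1:2, sum(surv), TRUE, prob = c(0.8, 0.2)) / two_n
    } else {
      fnew[surv] <- freq[ext_sites, pe][surv]
    }
    freq[ext_sites, pe] <- fnew
  }

  ## assemble per-site truth: positions, alt base, per-pop frequency
  alt_of <- function(ref) {
    ## deterministic alternate: next base in A->C->G->T->A cycle
    cyc <- c(A = "C", C = "G", G = "T", T = "A")
    unname(cyc[ref])
  }
  all_pos <- c(poly_pos, special_pos)
  all_freq <- freq
  if (!is.null(fs)) all_freq <- rbind(all_freq, matrix(fs$freq, 1L))
  if (nrow(cfg$outlier_snps)) {
    fm <- as.matrix(cfg$outlier_snps[, paste0("freq_pop", seq_len(np)),
                                     with = FALSE])
    all_freq <- rbind(all_freq, fm)
  }
  ord <- order(all_pos)
  all_pos <- all_pos[ord]
  all_freq <- all_freq[ord, , drop = FALSE]
  ref_at <- genome[all_pos]
  alt_at <- alt_of(ref_at)
  if (!is.null(fs)) {
    ## the kdr-like SNP is C->T (Leu CTT -> Phe TTT)
    alt_at[all_pos == fs$position] <- "T"
  }

  ## read counts per population for every genomic position
  base_idx <- match(genome, c("A", "T", "C", "G"))
  snp_row <- match(seq_len(L), all_pos)        # NA for monomorphic sites
  pool_counts <- matrix(NA_integer_, length(all_pos), np)
  counts <- vector("list", np)
  for (p in seq_len(np)) {
    depth <- stats::rpois(L, cfg$depth_mean)
    m <- matrix(0L, L, 4L, dimnames = list(NULL, c("A", "T", "C", "G")))
    ## monomorphic: all reads on the reference base
    m[cbind(seq_len(L), base_idx)] <- depth
    ## polymorphic: pool allele count ~ Binomial(2n, freq); reads cover
    ## distinct template chromosomes (duplicates are removed upstream in
    ## the emulated pipeline), so up to 2n reads are drawn without
    ## replacement (hypergeometric) and only depth beyond 2n resamples
    ## binomially. This keeps the read sample a true chromosome sample,
    ## so classic sample-size-n statistics stay calibrated, while read
    ## fractions still converge to pool fractions as depth grows.
    isnp <- which(!is.na(snp_row))
    r <- snp_row[isnp]
    ## with drift the pool is a binomial sample of 2n chromosomes at the
    ## population frequency; without drift (nu = Inf) the SFS draw itself
    ## is the pool's sample SFS (a sample from a neutral population has
    ## spectrum 1/i), so the pool count is taken deterministically
    pool_alt <- if (is.infinite(nu)) {
      as.integer(round(all_freq[r, p] * two_n))
    } else {
      stats::rbinom(length(isnp), two_n, all_freq[r, p])
    }
    pool_counts[r, p] <- pool_alt
    d1 <- pmin(depth[isnp], two_n)
    alt_reads <- as.integer(stats::rhyper(length(isnp), pool_alt,
                                          two_n - pool_alt, d1))
    extra <- depth[isnp] - d1
    over <- extra > 0L
    if (any(over)) {
      alt_reads[over] <- alt_reads[over] +
        stats::rbinom(sum(over), extra[over], pool_alt[over] / two_n)
    }
    ai <- match(alt_at[r], c("A", "T", "C", "G"))
    ri <- base_idx[isnp]
    m[cbind(isnp, ri)] <- depth[isnp] - alt_reads
    m[cbind(isnp, ai)] <- m[cbind(isnp, ai)] + alt_reads
    counts[[p]] <- apply_seq_error(m, cfg$error_rate)
  }

  sync <- data.table::data.table(chrom = cfg$chrom, pos = seq_len(L),
                                 ref = genome)
  for (p in seq_len(np)) {
    m <- counts[[p]]
    for (j in 1:4) {
      data.table::set(sync, j = paste0(SYNC_BASES[j], p), value = m[, j])
    }
    data.table::set(sync, j = paste0("N", p), value = 0L)
    data.table::set(sync, j = paste0("D", p), value = 0L)
  }
  sync <- as_pooled_counts(sync, np)

  snp_truth <- data.table::data.table(
    chrom = cfg$chrom, pos = all_pos, ref = ref_at, alt = alt_at,
    type = ifelse(!is.null(fs) & all_pos %in% fs$position, "fixed",
                  ifelse(all_pos %in% cfg$outlier_snps$pos, "outlier",
                         "background")))
  for (p in seq_len(np)) {
    data.table::set(snp_truth, j = paste0("freq_pop", p),
                    value = all_freq[, p])
  }
  truth <- list(sweep_core = core,
                sweep_extension = if (!is.null(ext)) {
                  c(start = ext$start, end = ext$end)
                },
                extension_population = if (!is.null(ext)) ext$population,
                snps = snp_truth, poly_pos = poly_pos,
                pool_counts = pool_counts)

  fasta <- stats::setNames(paste(genome, collapse = ""), cfg$chrom)
  out <- list(sync = sync, fasta = fasta, genes = genes, truth = truth,
              config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(sync = file.path(out_dir, "sim.sync"),
               gff = file.path(out_dir, "sim.gff3"),
               fasta = file.path(out_dir, "sim.fasta"),
               truth_snps = file.path(out_dir, "truth_snps.tsv"),
               truth_regions = file.path(out_dir, "truth_regions.tsv"))
    write_sync(sync, paths[["sync"]])
    write_gff(genes, paths[["gff"]])
    write_fasta(fasta, paths[["fasta"]])
    data.table::fwrite(snp_truth, paths[["truth_snps"]], sep = "\t")
    regions <- data.table::data.table(
      region = c(if (!is.null(core)) "sweep_core",
                 if (!is.null(ext)) "sweep_extension"),
      start = c(if (!is.null(core)) core[1], if (!is.null(ext)) ext$start),
      end = c(if (!is.null(core)) core[2], if (!is.null(ext)) ext$end),
      population = c(if (!is.null(core)) "all",
                     if (!is.null(ext)) as.character(ext$population)))
    data.table::fwrite(regions, paths[["truth_regions"]], sep = "\t")
    out$paths <- paths
  }
  out
}

## Gene layout: a kdr-like host gene around the fixed SNP (codon position
## 1 at the SNP), a zero-diversity "kish-like" gene in the core, a
## minus-strand gene in the extension, and two background genes.
sim_genes <- function(cfg) {
  fs <- cfg$fixed_snp
  core <- cfg$sweep_core
  ext <- cfg$sweep_extension
  genes <- list()
  if (!is.null(fs)) {
    s <- fs$position - 2799L          # offset 2799 -> codon index 934
    genes$para_like <- gene_model("para_like", cfg$chrom, "+",
                                  cbind(s, s + 2999L),
                                  name = "sodium_channel_para_like")
  }
  if (!is.null(core)) {
    kish_s <- core[1] + 1000L
    genes$kish_like <- gene_model("kish_like", cfg$chrom, "+",
                                  cbind(kish_s, kish_s + 599L),
                                  name = "protein_kish_like")
  }
  if (!is.null(ext)) {
    kl9_s <- as.integer(ext$start + 2000L)
    genes$kl9_like <- gene_model("kl9_like", cfg$chrom, "-",
                                 cbind(kl9_s, kl9_s + 899L),
                                 name = "kruppel_like_factor9")
  }
  bg1 <- as.integer(max(1L, (if (!is.null(core)) core[1] else
                             cfg$genome_length %/% 2L) - 60000L))
  genes$bg_1 <- gene_model("bg_1", cfg$chrom, "+",
                           cbind(c(bg1, bg1 + 2000L),
                                 c(bg1 + 899L, bg1 + 2599L)),
                           name = "background_gene_1")
  bg2 <- as.integer(min(cfg$genome_length - 2000L,
                        (if (!is.null(ext)) ext$end else
                         cfg$genome_length %/% 2L) + 50000L))
  genes$bg_2 <- gene_model("bg_2", cfg$chrom, "-",
                           cbind(bg2, bg2 + 1199L),
                           name = "background_gene_2")
  genes
}
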