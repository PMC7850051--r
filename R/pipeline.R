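## pipeline_cli: orchestrate simulate -> diversity -> sweep -> fst -> pca
## -> screen -> probit from one config, with logging, a checksum manifest,
## and seeded reproducibility. A single global seed is expanded into
## per-stage seeds by a fixed derivation so stages are individually
## reproducible.

#' Pipeline run configuration
#'
#' Collects every stage parameter with the analysis defaults: 5-kb
#' windows, target coverage 50, max coverage 100, min allele count 2,
#' min covered fraction 0.6, 10,000 bootstrap replicates at 90% CI, 1%
#' distribution tails, K = 2 components, FDR q 0.05, pi threshold 0.002.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param sim a [sim_config] to generate inputs, or NULL to read `paths`.
#' @param paths named list/vector with `sync`, `gff`, `fasta` (used when
#'   `sim` is NULL); `n_populations` is then required.
#' @param n_populations population count when reading external inputs.
#' @param pool_sizes diploid pool sizes (default 100 each).
#' @param window,target_coverage,max_coverage,min_count,min_covered_fraction
#'   diversity-stage parameters.
#' @param bootstrap_reps,ci_level,tail_q sweep-stage parameters.
#' @param pi_threshold,max_gap_windows sweep delineation parameters.
#' @param K,fdr_q PCA-stage parameters.
#' @param assay_csv optional dose-response CSV; NULL simulates a
#'   demonstration assay (three populations, resistance ratio ~3).
#' @param seed global seed; per-stage seeds are derived as
#'   `seed * 101 + stage_index`.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, sim = sim_config(), paths = NULL,
                       n_populations = if (!is.null(sim)) sim$n_populations else NULL,
                       pool_sizes = rep(100L, n_populations),
                       window = 5000L, target_coverage = 50L,
                       max_coverage = 100L, min_count = 2L,
                       min_covered_fraction = 0.6,
                       bootstrap_reps = 10000L, ci_level = 0.90,
                       tail_q = 0.01, pi_threshold = 0.002,
                       max_gap_windows = 1L, K = 2L, fdr_q = 0.05,
                       assay_csv = NULL, seed = 1L) {
  if (is.null(sim) && is.null(paths)) {
    stop("run_config: need either a sim config or input paths")
  }
  if (is.null(n_populations)) stop("run_config: n_populations is required")
  stopifnot(window >= 1, target_coverage > 0,
            target_coverage <= max_coverage, min_count >= 1,
            min_covered_fraction > 0, min_covered_fraction <= 1,
            bootstrap_reps >= 1, ci_level > 0, ci_level < 1, tail_q > 0,
            tail_q < 0.5, pi_threshold > 0, max_gap_windows >= 0, K >= 1,
            fdr_q > 0, fdr_q < 1, length(pool_sizes) == n_populations)
  structure(list(out_dir = out_dir, sim = sim, paths = paths,
                 n_populations = as.integer(n_populations),
                 pool_sizes = as.integer(pool_sizes),
                 window = as.integer(window),
                 target_coverage = as.integer(target_coverage),
                 max_coverage = as.integer(max_coverage),
                 min_count = as.integer(min_count),
                 min_covered_fraction = min_covered_fraction,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 ci_level = ci_level, tail_q = tail_q,
                 pi_threshold = pi_threshold,
                 max_gap_windows = as.integer(max_gap_windows),
                 K = as.integer(K), fdr_q = fdr_q, assay_csv = assay_csv,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a plain-text key = value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment; commas make
#' vectors; numeric-looking values are converted. Keys are the arguments
#' of [run_config] plus any `sim.`-prefixed [sim_config] argument.
#'
#' @param path config file path.
#' @param out_dir output directory (may also be given as a key).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  parse_val <- function(s) {
    s <- trimws(strsplit(trimws(s), ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(s))
    if (!anyNA(num)) num else s
  }
  vals <- lapply(kv, function(m) parse_val(m[3]))
  names(vals) <- vapply(kv, function(m) trimws(m[2]), "")
  sim_keys <- startsWith(names(vals), "sim.")
  sim_args <- vals[sim_keys]
  names(sim_args) <- sub("^sim\\.", "", names(sim_args))
  ## structured sim keys: "none" disables a region; sweep_extension is
  ## "start, end, population"; fixed_snp is "position, freq1, freq2, ..."
  for (k in names(sim_args)) {
    v <- sim_args[[k]]
    if (identical(v, "none")) sim_args[k] <- list(NULL)
  }
  if (is.numeric(sim_args$sweep_extension)) {
    v <- sim_args$sweep_extension
    sim_args$sweep_extension <- list(start = v[1], end = v[2],
                                     population = as.integer(v[3]))
  }
  if (is.numeric(sim_args$fixed_snp)) {
    v <- sim_args$fixed_snp
    sim_args$fixed_snp <- list(position = as.integer(v[1]), freq = v[-1])
  }
  run_args <- vals[!sim_keys]
  if (!is.null(out_dir)) run_args$out_dir <- out_dir
  sim <- if (length(sim_args) || is.null(run_args$paths)) {
    do.call(sim_config, sim_args)
  } else NULL
  do.call(run_config, c(run_args, list(sim = sim)))
}

stage_seed <- function(cfg, i) (cfg$seed * 101L + i) %% .Machine$integer.max

#' Run the full pipeline
#'
#' Stages run in dependency order: simulate (or load), diversity, sweep,
#' fst, pca, screen, probit. Every output file is listed in a manifest
#' with md5 checksums; an identical config + seed yields identical
#' checksums. Any stage error aborts with the stage name.
#'
#' @param cfg a [run_config].
#' @param stages subset of stages to run (default all; "simulate" alone
#'   writes only the synthetic inputs).
#' @param quiet suppress progress logging.
#' @return data.table manifest (stage, file, md5), written to
#'   `manifest.tsv` in `out_dir`.
#' @export
run_all <- function(cfg, stages = c("simulate", "diversity", "sweep",
                                    "fst", "pca", "screen", "probit"),
                    quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) if (!quiet) message("[poolsweep] ", ...)
  manifest <- list()
  add <- function(stage, files) {
    manifest[[length(manifest) + 1L]] <<- data.table::data.table(
      stage = stage, file = basename(unname(files)),
      md5 = unname(tools::md5sum(unname(files))))
  }
  params <- subsample_params(cfg$target_coverage, cfg$max_coverage,
                             cfg$min_count, cfg$min_covered_fraction,
                             seed = stage_seed(cfg, 2L))
  run_stage <- function(name, expr) {
    log_line("stage ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## --- inputs ---------------------------------------------------------
  sim <- NULL
  if (!is.null(cfg$sim)) {
    simcfg <- cfg$sim
    simcfg$seed <- stage_seed(cfg, 1L)
    if ("simulate" %in% stages) {
      sim <- run_stage("simulate", simulate_pools(simcfg, out_dir = cfg$out_dir))
      add("simulate", sim$paths)
    } else {
      sim <- run_stage("simulate", simulate_pools(simcfg))
    }
    sync <- sim$sync; genes <- sim$genes; fasta <- sim$fasta
  } else {
    sync <- run_stage("load", read_sync(cfg$paths[["sync"]], cfg$n_populations))
    genes <- run_stage("load", read_gff(cfg$paths[["gff"]]))
    fasta <- run_stage("load", read_fasta(cfg$paths[["fasta"]]))
  }
  genome_length <- if (!is.null(sim)) sim$config$genome_length else max(sync$pos)
  if (identical(stages, "simulate")) {
    return(write_manifest(manifest, cfg$out_dir))
  }

  ## --- diversity ------------------------------------------------------
  windows <- NULL
  if (any(c("diversity", "sweep", "screen") %in% stages)) {
    windows <- run_stage("diversity", {
      set.seed(stage_seed(cfg, 2L))
      w <- diversity_scan(sync, params, cfg$window, genome_length)
      files <- character()
      for (p in sort(unique(w$population))) {
        f <- file.path(cfg$out_dir, sprintf("diversity_pop%d.tsv", p))
        write_report(w[population == p], f, "window_stats")
        files <- c(files, f)
      }
      gp <- gene_pi_scan(sync, genes, params)
      gp_files <- character()
      for (p in sort(unique(gp$population))) {
        f <- file.path(cfg$out_dir, sprintf("gene_pi_pop%d.tsv", p))
        write_report(gp[population == p], f, "gene_pi")
        gp_files <- c(gp_files, f)
      }
      add("diversity", c(files, gp_files))
      w
    })
  }

  ## --- sweep ----------------------------------------------------------
  sweep_core <- NULL
  if (any(c("sweep", "screen") %in% stages)) {
    sw <- run_stage("sweep", {
      res <- sweep_scan(windows, genes, cfg$pi_threshold,
                        cfg$max_gap_windows)
      tj <- data.table::rbindlist(lapply(sort(unique(windows$population)),
        function(p) {
          tt <- tajima_tails(windows[population == p], q = cfg$tail_q,
                             reps = cfg$bootstrap_reps,
                             level = cfg$ci_level,
                             seed = stage_seed(cfg, 3L) + p)
          data.table::data.table(population = as.character(p),
                                 genome_mean = tt$summary$genome_mean,
                                 ci_low = tt$summary$ci_low,
                                 ci_high = tt$summary$ci_high,
                                 lower_tail_cutoff = tt$summary$lower_tail_cutoff,
                                 upper_tail_cutoff = tt$summary$upper_tail_cutoff)
        }))
      f1 <- file.path(cfg$out_dir, "sweep_regions.tsv")
      reg <- data.table::copy(res$regions)
      if (nrow(reg)) {
        reg[, populations := as.character(population)]
        if (!"genes" %in% names(reg)) reg[, genes := ""]
      } else {
        reg <- data.table::data.table(chrom = character(),
                                      start = integer(), end = integer(),
                                      populations = character(),
                                      min_pi = numeric(),
                                      mean_pi = numeric(),
                                      n_windows = integer(),
                                      flank_pi = numeric(),
                                      genes = character())
      }
      write_report(reg, f1, "sweep_regions")
      f2 <- file.path(cfg$out_dir, "tajima_summary.tsv")
      write_report(tj, f2, "tajima_summary")
      add("sweep", c(f1, f2))
      res
    })
    if (!is.null(sw$intersection$core)) {
      sweep_core <- sw$intersection$core
    }
  }

  ## --- fst ------------------------------------------------------------
  if ("fst" %in% stages) {
    run_stage("fst", {
      set.seed(stage_seed(cfg, 4L))
      fr <- fst_scan(sync, cfg$pool_sizes, params)
      f1 <- file.path(cfg$out_dir, "fst_per_snp.tsv")
      write_report(fr$per_snp, f1, "fst_snp")
      excl_region <- if (!is.null(sweep_core)) sweep_core
                     else if (!is.null(sim)) sim$truth$sweep_core else NULL
      nosweep <- if (!is.null(excl_region)) {
        fst_excluding(fr$per_snp, excl_region)
      } else fr$summary
      summ <- merge(fr$summary,
                    nosweep[, .(pop_pair,
                                fst_classical_nosweep = fst_classical,
                                fst_anova_nosweep = fst_anova)],
                    by = "pop_pair")
      f2 <- file.path(cfg$out_dir, "fst_summary.tsv")
      write_report(summ, f2, "fst_summary")
      f3 <- file.path(cfg$out_dir, "fst_outliers.tsv")
      write_report(fst_outliers(fr$per_snp, q = cfg$tail_q), f3, "fst_snp")
      add("fst", c(f1, f2, f3))
    })
  }

  ## --- pca ------------------------------------------------------------
  if ("pca" %in% stages) {
    run_stage("pca", {
      set.seed(stage_seed(cfg, 5L))
      res <- suppressWarnings(pca_outlier_scan(sync, params, K = cfg$K))
      f <- file.path(cfg$out_dir, "pca_outliers.tsv")
      write_report(res[, .(chrom, pos, d2, p_value, q_value)], f,
                   "pca_outliers")
      add("pca", f)
    })
  }

  ## --- screen ---------------------------------------------------------
  if ("screen" %in% stages) {
    run_stage("screen", {
      set.seed(stage_seed(cfg, 6L))
      region <- if (!is.null(sweep_core)) {
        unname(c(sweep_core[["start"]], sweep_core[["end"]]))
      } else NULL
      sc <- screen_region(sync, genes, fasta, region = region,
                          min_count = cfg$min_count)
      np <- n_pops(sync)
      frac_cols <- paste0("frac_pop", seq_len(np))
      fr_mat <- as.matrix(sc[, frac_cols, with = FALSE])
      sc[, fractions := if (nrow(sc)) {
        apply(fr_mat, 1L, function(r) paste(sprintf("%.4f", r), collapse = ","))
      } else character(0)]
      f <- file.path(cfg$out_dir, "variant_screen.tsv")
      write_report(sc, f, "variant_calls")
      add("screen", f)
    })
  }

  ## --- probit ---------------------------------------------------------
  if ("probit" %in% stages) {
    run_stage("probit", {
      assay <- if (!is.null(cfg$assay_csv)) {
        read_assay(cfg$assay_csv)
      } else {
        ## demonstration bioassay: two susceptible-like populations and a
        ## ~3x resistant one, at the standard design
        data.table::rbindlist(list(
          simulate_assay(7.45, 2, population = "pop1",
                         seed = stage_seed(cfg, 7L)),
          simulate_assay(7.20, 2, population = "pop2",
                         seed = stage_seed(cfg, 8L)),
          simulate_assay(24.27, 2, population = "pop3",
                         seed = stage_seed(cfg, 9L))))
      }
      pr <- probit_scan(assay)
      f <- file.path(cfg$out_dir, "probit.tsv")
      write_report(pr, f, "probit")
      add("probit", f)
    })
  }

  write_manifest(manifest, cfg$out_dir)
}

write_manifest <- function(manifest, out_dir) {
  m <- data.table::rbindlist(manifest)
  data.table::setorder(m, stage, file)
  data.table::fwrite(m, file.path(out_dir, "manifest.tsv"), sep = "\t")
  m[]
}
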