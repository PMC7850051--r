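## io: sync / GFF3 / FASTA / TSV report reading and writing.
##
## Coordinates are 1-based inclusive throughout (pileup/sync/GFF convention).
## Sync count order per population is A:T:C:G:N:del; N and del are parsed but
## excluded from coverage and from every statistic.

SYNC_BASES <- c("A", "T", "C", "G", "N", "D")
ACGT <- c("A", "T", "C", "G")

#' Read a Popoolation2-style sync file
#'
#' Parses tab-separated pooled allele counts: chromosome, 1-based position,
#' reference base, then one `A:T:C:G:N:del` colon-separated sextuplet per
#' population. Malformed rows raise errors naming the offending line; they
#' are never silently skipped.
#'
#' @param path path to a sync file.
#' @param n_populations expected number of population count columns.
#' @return a `pooled_counts` object: a [data.table::data.table] with columns
#'   `chrom`, `pos`, `ref` and integer columns `A1,T1,C1,G1,N1,D1, A2,...`
#'   (one block of six per population), plus attribute `n_pops`.
#' @export
read_sync <- function(path, n_populations) {
  if (!file.exists(path)) stop("sync file does not exist: ", path)
  if (n_populations < 1) stop("n_populations must be >= 1")
  n_expected <- 3L + as.integer(n_populations)
  raw <- data.table::fread(path, sep = "\t", header = FALSE,
                           colClasses = "character", fill = TRUE,
                           quote = "", strip.white = FALSE)
  if (nrow(raw) == 0L) return(empty_pooled_counts(n_populations))
  if (ncol(raw) != n_expected) {
    stop(sprintf("sync format error: expected %d tab fields (3 + %d populations) but file has %d columns (line 1)",
                 n_expected, n_populations, ncol(raw)))
  }
  bad <- which(!stats::complete.cases(raw) |
                 Reduce(`|`, lapply(raw, function(col) col == "")))
  if (length(bad)) {
    stop(sprintf("sync format error: wrong number of fields at line %d", bad[1]))
  }
  out <- data.table::data.table(chrom = raw[[1L]],
                                pos = suppressWarnings(as.integer(raw[[2L]])),
                                ref = toupper(raw[[3L]]))
  if (anyNA(out$pos) || any(out$pos < 1L)) {
    stop(sprintf("sync parse error: non-integer or non-positive position at line %d",
                 which(is.na(out$pos) | out$pos < 1L)[1]))
  }
  if (!all(out$ref %chin% c(ACGT, "N"))) {
    stop(sprintf("sync parse error: reference base not in {A,C,G,T,N} at line %d",
                 which(!(out$ref %chin% c(ACGT, "N")))[1]))
  }
  for (p in seq_len(n_populations)) {
    parts <- data.table::tstrsplit(raw[[3L + p]], ":", fixed = TRUE)
    if (length(parts) != 6L) {
      stop(sprintf("sync parse error: population %d counts are not colon-separated sextuplets", p))
    }
    for (j in seq_len(6L)) {
      v <- suppressWarnings(as.integer(parts[[j]]))
      bad <- which(is.na(v) | v < 0L)
      if (length(bad)) {
        stop(sprintf("sync parse error: non-integer count for population %d at line %d", p, bad[1]))
      }
      data.table::set(out, j = paste0(SYNC_BASES[j], p), value = v)
    }
  }
  as_pooled_counts(out, n_populations)
}

as_pooled_counts <- function(dt, n_pops) {
  data.table::setattr(dt, "n_pops", as.integer(n_pops))
  data.table::setattr(dt, "class", c("pooled_counts", class(dt)))
  dt
}

empty_pooled_counts <- function(n_pops) {
  dt <- data.table::data.table(chrom = character(), pos = integer(),
                               ref = character())
  for (p in seq_len(n_pops)) {
    for (b in SYNC_BASES) data.table::set(dt, j = paste0(b, p), value = integer())
  }
  as_pooled_counts(dt, n_pops)
}

#' Number of populations in a pooled_counts object
#' @param x a `pooled_counts` object.
#' @return integer count of population columns.
#' @export
n_pops <- function(x) attr(x, "n_pops", exact = TRUE)

#' Extract the A,T,C,G count matrix for one population
#'
#' @param x a `pooled_counts` object.
#' @param pop population index (1-based).
#' @return integer matrix, one row per site, columns A,T,C,G. N and del
#'   counts are excluded (they never enter any statistic).
#' @export
count_matrix <- function(x, pop) {
  cols <- paste0(ACGT, pop)
  m <- as.matrix(x[, cols, with = FALSE])
  colnames(m) <- ACGT
  m
}

#' Per-site coverage (A+T+C+G) for each population
#' @param x a `pooled_counts` object.
#' @return integer matrix, sites x populations.
#' @export
coverage_matrix <- function(x) {
  np <- n_pops(x)
  out <- matrix(0L, nrow = nrow(x), ncol = np)
  for (p in seq_len(np)) out[, p] <- rowSums(count_matrix(x, p))
  out
}

#' Write a pooled_counts object to sync format
#' @param x a `pooled_counts` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sync <- function(x, path) {
  np <- n_pops(x)
  cols <- list(x$chrom, x$pos, x$ref)
  for (p in seq_len(np)) {
    blk <- as.matrix(x[, paste0(SYNC_BASES, p), with = FALSE])
    cols[[3L + p]] <- paste(blk[, 1], blk[, 2], blk[, 3], blk[, 4],
                            blk[, 5], blk[, 6], sep = ":")
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

## ---- gene models -----------------------------------------------------------

#' Construct a gene model
#'
#' @param gene_id identifier (the mRNA ID in GFF3 input).
#' @param chrom sequence identifier.
#' @param strand "+" or "-".
#' @param cds_intervals two-column matrix of 1-based inclusive \[start,end\]
#'   CDS intervals; must be non-overlapping once sorted by start.
#' @param name free-text gene name.
#' @param complete logical; when TRUE the total CDS length must be divisible
#'   by 3.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds_intervals, name = gene_id,
                       complete = TRUE) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-': ", gene_id)
  iv <- matrix(as.integer(cds_intervals), ncol = 2L,
               dimnames = list(NULL, c("start", "end")))
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  if (any(iv[, 2L] < iv[, 1L])) stop("gene ", gene_id, ": interval end < start")
  if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L])) {
    stop("gene ", gene_id, ": overlapping CDS intervals")
  }
  len <- sum(iv[, 2L] - iv[, 1L] + 1L)
  if (complete && len %% 3L != 0L) {
    stop("gene ", gene_id, ": CDS length ", len,
         " not divisible by 3 but model is flagged complete")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds_intervals = iv, name = name, complete = complete,
                 cds_length = len),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d strand %s, %d CDS interval(s), %d bp\n",
              x$gene_id, x$name, x$chrom, min(x$cds_intervals[, 1]),
              max(x$cds_intervals[, 2]), x$strand, nrow(x$cds_intervals),
              x$cds_length))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' One `gene_model` per mRNA feature; CDS rows are attached via their
#' `Parent` attribute. A CDS without a Parent, or overlapping CDS intervals
#' within one model, raise errors. An mRNA may carry `complete=false` to
#' exempt it from the length-divisible-by-3 invariant.
#'
#' @param path path to a GFF3 file.
#' @return named list of [gene_model] objects, keyed by gene_id.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("GFF3 file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(list())
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fields) != 9L) stop("GFF3 format error: expected 9 tab fields")
  gff <- data.table::data.table(chrom = fields[[1]], type = fields[[3]],
                                start = as.integer(fields[[4]]),
                                end = as.integer(fields[[5]]),
                                strand = fields[[7]], attr = fields[[9]])
  gattr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attr))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  mrna <- gff[type == "mRNA"]
  cds <- gff[type == "CDS"]
  cds_parent <- gattr(cds$attr, "Parent")
  if (anyNA(cds_parent)) stop("GFF3 error: CDS feature without a Parent attribute")
  mrna_id <- gattr(mrna$attr, "ID")
  mrna_name <- gattr(mrna$attr, "Name")
  mrna_complete <- tolower(gattr(mrna$attr, "complete"))
  models <- vector("list", nrow(mrna))
  for (i in seq_len(nrow(mrna))) {
    rows <- which(cds_parent == mrna_id[i])
    if (!length(rows)) next
    models[[i]] <- gene_model(
      gene_id = mrna_id[i], chrom = mrna$chrom[i], strand = mrna$strand[i],
      cds_intervals = cbind(cds$start[rows], cds$end[rows]),
      name = if (is.na(mrna_name[i])) mrna_id[i] else mrna_name[i],
      complete = !identical(mrna_complete[i], "false"))
  }
  keep <- !vapply(models, is.null, TRUE)
  models <- models[keep]
  names(models) <- mrna_id[keep]
  models
}

#' Write gene models to a GFF3 file
#' @param models list of [gene_model] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff <- function(models, path) {
  out <- c("##gff-version 3")
  for (g in models) {
    span <- range(g$cds_intervals)
    out <- c(out,
             sprintf("%s\tpoolsweep\tgene\t%d\t%d\t.\t%s\t.\tID=gene_%s",
                     g$chrom, span[1], span[2], g$strand, g$gene_id),
             sprintf("%s\tpoolsweep\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene_%s;Name=%s;complete=%s",
                     g$chrom, span[1], span[2], g$strand, g$gene_id,
                     g$gene_id, g$name, if (g$complete) "true" else "false"),
             sprintf("%s\tpoolsweep\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                     g$chrom, g$cds_intervals[, 1], g$cds_intervals[, 2],
                     g$strand, g$gene_id))
  }
  writeLines(out, path)
  invisible(path)
}

## ---- FASTA -----------------------------------------------------------------

#' Read a FASTA file into a named character vector
#' @param path path to an uncompressed FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) stop("not a FASTA file: ", path)
  id <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  stats::setNames(toupper(seqs), id)
}

#' Write named sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## ---- TSV reports -----------------------------------------------------------

#' Column schemas for TSV reports
#'
#' Each schema maps output column names to types (`chr`, `int`, `num`,
#' `lgl`). Floats are written at fixed 6-decimal precision so repeated
#' writes are byte-identical.
#' @export
report_schemas <- list(
  window_stats = c(chrom = "chr", start = "int", end = "int", pi = "num",
                   thetaW = "num", tajD = "num", snps = "int",
                   covered_frac = "num", valid = "lgl"),
  gene_pi = c(gene_id = "chr", pi = "num", n_snps = "int",
              mean_coverage = "num", usable = "lgl"),
  sweep_regions = c(chrom = "chr", start = "int", end = "int",
                    populations = "chr", min_pi = "num", mean_pi = "num",
                    n_windows = "int", flank_pi = "num", genes = "chr"),
  tajima_summary = c(population = "chr", genome_mean = "num", ci_low = "num",
                     ci_high = "num", lower_tail_cutoff = "num",
                     upper_tail_cutoff = "num"),
  fst_snp = c(chrom = "chr", pos = "int", pop_pair = "chr",
              fst_classical = "num", fst_anova = "num"),
  fst_window = c(chrom = "chr", start = "int", end = "int", pop_pair = "chr",
                 fst_classical = "num", fst_anova = "num", n_snps = "int"),
  fst_summary = c(pop_pair = "chr", fst_classical = "num", fst_anova = "num",
                  fst_classical_nosweep = "num", fst_anova_nosweep = "num",
                  n_snps = "int"),
  pca_outliers = c(chrom = "chr", pos = "int", d2 = "num", p_value = "num",
                   q_value = "num"),
  variant_calls = c(chrom = "chr", pos = "int", ref = "chr", alt = "chr",
                    gene_id = "chr", consequence = "chr", aa_change = "chr",
                    conservative = "lgl", fractions = "chr"),
  probit = c(population = "chr", slope = "num", intercept = "num",
             lc50 = "num", ci_low = "num", ci_high = "num", deviance = "num",
             heterogeneity = "lgl")
)

#' Write records as a TSV report
#'
#' Tab-separated with a header row; numeric columns at fixed 6-decimal
#' precision; `NA` written literally. Writing the same records twice yields
#' byte-identical files.
#'
#' @param records data.frame/data.table conforming to `schema`.
#' @param path output path.
#' @param schema either a name in [report_schemas] or a named character
#'   vector of column types.
#' @return invisibly, `path`.
#' @export
write_report <- function(records, path, schema) {
  if (is.character(schema) && length(schema) == 1L) {
    if (!schema %in% names(report_schemas)) stop("unknown schema: ", schema)
    schema <- report_schemas[[schema]]
  }
  cols <- names(schema)
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("records do not conform to schema; missing columns: ",
         paste(missing, collapse = ", "))
  }
  out <- data.table::as.data.table(records)[, cols, with = FALSE]
  for (j in cols) {
    v <- out[[j]]
    txt <- switch(schema[[j]],
      num = ifelse(is.na(v), "NA", sprintf("%.6f", as.numeric(v))),
      int = ifelse(is.na(v), "NA", format(as.integer(v), scientific = FALSE, trim = TRUE)),
      lgl = ifelse(is.na(v), "NA", ifelse(as.logical(v), "TRUE", "FALSE")),
      chr = ifelse(is.na(v), "NA", as.character(v)),
      stop("unknown column type: ", schema[[j]]))
    data.table::set(out, j = j, value = txt)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out)) writeLines(do.call(paste, c(out, sep = "\t")), con)
  invisible(path)
}

#' Read a TSV report written by [write_report]
#' @param path path to a report TSV.
#' @return a data.table.
#' @export
read_report <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
}
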