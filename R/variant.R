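## variant_screen: coding-consequence classification of segregating
## variants and per-population alternate-read fractions.
##
## "Conservative" amino-acid substitutions are defined as BLOSUM62 score
## >= 0 for the pair (configurable threshold/matrix). Codon numbering is
## 1-based from the annotated CDS start, matching the field's "L934F"
## convention; minus-strand genes are handled by reverse-complementing.

## Standard genetic code, DNA alphabet.
GENETIC_CODE_PS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

## BLOSUM62 substitution scores (upper triangle listed row-wise over the
## 20 standard amino acids in this order).
BLOSUM62_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
BLOSUM62 <- local({
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
        5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
           6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
              6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
                 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
                    5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
                       5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
                          6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
                             8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
                                4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
                                   4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
                                      5,-1,-3,-1, 0,-1,-3,-2,-2,
                                         5, 0,-2,-1,-1,-1,-1, 1,
                                            6,-4,-2,-2, 1, 3,-1,
                                               7,-1,-1,-4,-3,-2,
                                                  4, 1,-3,-2,-2,
                                                     5,-2,-2, 0,
                                                       11, 2,-3,
                                                           7,-1,
                                                              4)
  m <- matrix(0L, 20L, 20L, dimnames = list(BLOSUM62_AA, BLOSUM62_AA))
  k <- 1L
  for (i in 1:20) {            # v lists the upper triangle row-wise
    for (j in i:20) {
      m[i, j] <- as.integer(v[k])
      k <- k + 1L
    }
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
})

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE))
}

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_PS[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Is an amino-acid substitution conservative?
#'
#' A substitution is conservative when its BLOSUM62 score is strictly
#' positive (score >= threshold, default 1). Zero-score pairs such as
#' Leu/Phe — the classic knock-down-resistance change — count as
#' nonconservative.
#'
#' @param ref_aa,alt_aa single-letter amino acids.
#' @param threshold minimum substitution score to call conservative
#'   (default 1, i.e. strictly positive).
#' @param matrix substitution matrix (default BLOSUM62).
#' @return logical; NA for stop codons or unknown residues.
#' @export
is_conservative <- function(ref_aa, alt_aa, threshold = 1,
                            matrix = BLOSUM62) {
  if (!ref_aa %in% rownames(matrix) || !alt_aa %in% rownames(matrix)) {
    return(NA)
  }
  matrix[ref_aa, alt_aa] >= threshold
}

## CDS-relative offset (0-based) of a genomic position within a gene model,
## on the coding strand. NA when pos is not in the CDS.
cds_offset <- function(gene, pos) {
  iv <- gene$cds_intervals
  off <- NA_integer_
  cum <- 0L
  for (k in seq_len(nrow(iv))) {
    if (pos >= iv[k, 1L] && pos <= iv[k, 2L]) {
      off <- cum + (pos - iv[k, 1L])
      break
    }
    cum <- cum + (iv[k, 2L] - iv[k, 1L] + 1L)
  }
  if (is.na(off)) return(NA_integer_)
  if (gene$strand == "-") gene$cds_length - 1L - off else off
}

## Spliced CDS sequence on the coding strand.
cds_sequence <- function(gene, chrom_seq) {
  iv <- gene$cds_intervals
  parts <- vapply(seq_len(nrow(iv)), function(k) {
    substr(chrom_seq, iv[k, 1L], iv[k, 2L])
  }, "")
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

#' Classify a SNP's coding consequence within a gene model
#'
#' Locates the genomic position in the spliced CDS (reverse-complementing
#' minus-strand genes), substitutes the alternate base in its codon, and
#' translates with the standard genetic code. The amino-acid change label
#' is `RefAA` + codon index (1-based from the CDS start) + `AltAA`.
#'
#' @param chrom_seq the chromosome/scaffold sequence (character).
#' @param gene a [gene_model].
#' @param pos 1-based genomic position.
#' @param ref,alt reference and alternate bases (genomic strand).
#' @return list with consequence ("synonymous", "nonsynonymous" or
#'   "noncoding"), aa_change (e.g. "L934F"; NA unless nonsynonymous),
#'   ref_aa, alt_aa, codon_index, conservative flag.
#' @export
classify_snp <- function(chrom_seq, gene, pos, ref, alt) {
  genomic <- toupper(substr(chrom_seq, pos, pos))
  if (genomic != toupper(ref)) {
    stop(sprintf("classify_snp: reference mismatch at %d: FASTA has %s, ref is %s",
                 pos, genomic, ref))
  }
  off <- cds_offset(gene, pos)
  if (is.na(off)) {
    return(list(consequence = "noncoding", aa_change = NA_character_,
                ref_aa = NA_character_, alt_aa = NA_character_,
                codon_index = NA_integer_, conservative = NA))
  }
  cds <- cds_sequence(gene, chrom_seq)
  ref_c <- toupper(ref); alt_c <- toupper(alt)
  if (gene$strand == "-") {
    ref_c <- chartr("ACGT", "TGCA", ref_c)
    alt_c <- chartr("ACGT", "TGCA", alt_c)
  }
  codon_index <- off %/% 3L + 1L
  codon_pos <- off %% 3L + 1L
  codon <- substr(cds, (codon_index - 1L) * 3L + 1L, codon_index * 3L)
  if (nchar(codon) < 3L || grepl("N", codon)) {
    return(list(consequence = "noncoding", aa_change = NA_character_,
                ref_aa = NA_character_, alt_aa = NA_character_,
                codon_index = codon_index, conservative = NA))
  }
  stopifnot(substr(codon, codon_pos, codon_pos) == ref_c)
  alt_codon <- codon
  substr(alt_codon, codon_pos, codon_pos) <- alt_c
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(alt_codon)
  if (identical(ref_aa, alt_aa)) {
    list(consequence = "synonymous", aa_change = NA_character_,
         ref_aa = ref_aa, alt_aa = alt_aa, codon_index = codon_index,
         conservative = NA)
  } else {
    list(consequence = "nonsynonymous",
         aa_change = paste0(ref_aa, codon_index, alt_aa),
         ref_aa = ref_aa, alt_aa = alt_aa, codon_index = codon_index,
         conservative = is_conservative(ref_aa, alt_aa))
  }
}

#' Alternate-allele read fraction per population
#'
#' @param counts A,T,C,G count vector, or sites x 4 matrix.
#' @param alt alternate base ("A", "T", "C" or "G"), recycled over rows.
#' @return alt reads / (A+T+C+G) coverage; NA at zero coverage.
#' @export
alt_read_fraction <- function(counts, alt) {
  m <- if (is.matrix(counts)) counts else matrix(as.numeric(counts), 1L,
                                                 dimnames = list(NULL, c("A", "T", "C", "G")))
  if (is.null(colnames(m))) colnames(m) <- c("A", "T", "C", "G")
  cov <- rowSums(m)
  alt <- rep(toupper(alt), length.out = nrow(m))
  a <- m[cbind(seq_len(nrow(m)), match(alt, colnames(m)))]
  ifelse(cov > 0, a / cov, NA_real_)
}

#' Screen a region's segregating variants for coding consequences
#'
#' All sites in `region` where a non-reference allele passes `min_count`
#' (summed over populations) are annotated with gene context, consequence,
#' amino-acid change, conservative flag, and per-population alternate-read
#' fractions. Sites with reference base N are excluded from
#' coding-consequence calls. Sites overlapping multiple gene models are
#' reported once per model.
#'
#' @param x a `pooled_counts` object.
#' @param genes list of [gene_model] objects.
#' @param fasta named character vector of chromosome sequences.
#' @param region `c(start, end)` or "chrom:start-end" string; NULL scans
#'   everything.
#' @param min_count minimum summed reads for the alternate allele
#'   (default 2).
#' @param nonsyn_only keep only nonsynonymous-and-nonconservative calls.
#' @return data.table of variant calls sorted by position, with one
#'   `frac_pop<i>` column per population.
#' @export
screen_region <- function(x, genes, fasta, region = NULL, min_count = 2L,
                          nonsyn_only = FALSE) {
  np <- n_pops(x)
  keep <- rep(TRUE, nrow(x))
  if (is.character(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4L) stop("bad region string: ", region)
    keep <- x$chrom == m[2] & x$pos >= as.integer(m[3]) & x$pos <= as.integer(m[4])
  } else if (!is.null(region)) {
    keep <- x$pos >= region[1] & x$pos <= region[2]
  }
  xs <- x[keep]
  mats <- lapply(seq_len(np), function(p) {
    m <- as.matrix(xs[, paste0(ACGT, p), with = FALSE]); colnames(m) <- ACGT; m
  })
  total <- Reduce(`+`, mats)
  ref_idx <- match(xs$ref, ACGT)      # NA for ref N
  nonref <- total
  nonref[cbind(seq_len(nrow(total)), ref_idx)[!is.na(ref_idx), , drop = FALSE]] <- 0L
  alt_idx <- max.col(nonref, ties.method = "first")
  alt_n <- nonref[cbind(seq_len(nrow(nonref)), alt_idx)]
  seg <- alt_n >= min_count & !is.na(ref_idx)
  idx <- which(seg)
  rows <- lapply(idx, function(i) {
    pos_i <- xs$pos[i]; chrom_i <- xs$chrom[i]
    alt_b <- ACGT[alt_idx[i]]
    fr <- vapply(mats, function(m) alt_read_fraction(m[i, ], alt_b), 0)
    hits <- Filter(function(g) {
      g$chrom == chrom_i && !is.na(cds_offset(g, pos_i))
    }, genes)
    base_row <- function(gene_id, cls) {
      dt <- data.table::data.table(
        chrom = chrom_i, pos = pos_i, ref = xs$ref[i], alt = alt_b,
        gene_id = gene_id, consequence = cls$consequence,
        aa_change = cls$aa_change, conservative = cls$conservative)
      for (p in seq_len(np)) {
        data.table::set(dt, j = paste0("frac_pop", p), value = fr[p])
      }
      dt
    }
    if (!length(hits)) {
      noncoding <- list(consequence = "noncoding", aa_change = NA_character_,
                        conservative = NA)
      return(base_row("intergenic", noncoding))
    }
    data.table::rbindlist(lapply(hits, function(g) {
      cls <- classify_snp(fasta[[chrom_i]], g, pos_i, xs$ref[i], alt_b)
      base_row(g$gene_id, cls)
    }))
  })
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) {
    out <- data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  gene_id = character(),
                                  consequence = character(),
                                  aa_change = character(),
                                  conservative = logical())
    for (p in seq_len(np)) {
      data.table::set(out, j = paste0("frac_pop", p), value = numeric())
    }
  }
  data.table::setorder(out, pos)
  if (nonsyn_only) {
    out <- out[consequence == "nonsynonymous" & conservative == FALSE]
  }
  out[]
}
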