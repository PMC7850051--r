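test_that("classify_snp handles the canonical kdr-like substitution", {
  # plus-strand gene, CDS 11..19, codons CTT GGG AAA
  seq <- paste0("NNNNNNNNNN", "CTTGGGAAA", "NN")
  g <- gene_model("g", "s", "+", cbind(11L, 19L))
  # CTT -> TTT at codon position 1: Leu -> Phe, nonconservative L1F
  r <- classify_snp(seq, g, 11L, "C", "T")
  expect_equal(r$consequence, "nonsynonymous")
  expect_equal(r$aa_change, "L1F")
  # BLOSUM62(L, F) = 0: not strictly positive, hence nonconservative
  expect_false(r$conservative)
  expect_true(is_conservative("L", "I"))   # score 2
  expect_false(is_conservative("D", "K"))  # score -1
  expect_true(is.na(is_conservative("*", "K")))
  # CTT -> CTG at codon position 3: synonymous
  r2 <- classify_snp(seq, g, 13L, "T", "G")
  expect_equal(r2$consequence, "synonymous")
  expect_true(is.na(r2$aa_change))
  # outside the CDS: noncoding
  expect_equal(classify_snp(seq, g, 5L, "N", "A")$consequence, "noncoding")
  # reference mismatch errors
  expect_error(classify_snp(seq, g, 11L, "G", "T"), "mismatch")
})

test_that("classify_snp handles minus-strand genes (hand-translated toy)", {
  # coding strand CDS = CTT GGG AAA; genomic plus strand holds its
  # reverse complement TTTCCCAAG at 11..19
  seq <- paste0("NNNNNNNNNN", "TTTCCCAAG", "NN")
  g <- gene_model("g", "s", "-", cbind(11L, 19L))
  # genomic pos 19 = first coding base (C of CTT); G->A genomic is C->T
  # coding: Leu -> Phe at codon 1
  r <- classify_snp(seq, g, 19L, "G", "A")
  expect_equal(r$consequence, "nonsynonymous")
  expect_equal(r$aa_change, "L1F")
  # genomic pos 11 = last coding base (codon 3 position 3): A->G coding
  # (T->C genomic): AAA -> AAG, Lys -> Lys synonymous
  r2 <- classify_snp(seq, g, 11L, "T", "C")
  expect_equal(r2$consequence, "synonymous")
})

test_that("classify_snp agrees with Biostrings over all sense codons x positions x substitutions, both strands", {
  skip_if_not_installed("Biostrings")
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]                  # 61 sense codons
  bases <- c("A", "C", "G", "T")
  revcomp1 <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  n_checked <- 0L
  for (codon in codons) {
    for (strand in c("+", "-")) {
      genomic_codon <- if (strand == "+") codon else revcomp1(codon)
      seq <- paste0("AAAA", genomic_codon, "AAAA")
      g <- gene_model("g", "s", strand, cbind(5L, 7L))
      for (cp in 1:3) {
        # genomic position of coding position cp
        pos <- if (strand == "+") 4L + cp else 8L - cp
        ref <- substr(seq, pos, pos)
        for (alt in setdiff(bases, ref)) {
          got <- classify_snp(seq, g, pos, ref, alt)
          alt_coding <- if (strand == "+") alt else revcomp1(alt)
          mut <- codon
          substr(mut, cp, cp) <- alt_coding
          aa_ref <- unname(gc[codon]); aa_alt <- unname(gc[mut])
          want <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
          expect_equal(got$consequence, want,
                       label = sprintf("%s[%d]%s->%s strand %s",
                                       codon, cp, ref, alt, strand))
          if (want == "nonsynonymous") {
            expect_equal(got$aa_change, paste0(aa_ref, 1L, aa_alt))
          }
          n_checked <- n_checked + 1L
        }
      }
    }
  }
  expect_equal(n_checked, 61L * 3L * 3L * 2L)
})

test_that("alt_read_fraction is the alternate share of ACGT coverage", {
  expect_equal(alt_read_fraction(c(A = 0, T = 50, C = 0, G = 0), "T"), 1.0)
  expect_equal(alt_read_fraction(c(A = 9, T = 41, C = 0, G = 0), "T"), 0.82)
  expect_equal(alt_read_fraction(c(A = 50, T = 0, C = 0, G = 0), "T"), 0.0)
  expect_true(is.na(alt_read_fraction(c(0, 0, 0, 0), "A")))
})

test_that("screen_region annotates segregating variants against truth", {
  sim <- simulate_pools(sweep_world(seed = 3L))
  core <- sim$truth$sweep_core
  sc <- screen_region(sim$sync, sim$genes, sim$fasta,
                      region = c(core[1], core[2]), min_count = 2)
  # the synthetic fixed kdr-like SNP: exactly one nonsynonymous call at
  # fraction 1.0 in all populations (eps = 0 leaves nothing else there)
  nonsyn <- sc[consequence == "nonsynonymous"]
  expect_equal(nrow(nonsyn), 1L)
  expect_equal(nonsyn$pos, sim$config$fixed_snp$position)
  expect_equal(nonsyn$aa_change, "L934F")
  expect_false(nonsyn$conservative)
  expect_equal(nonsyn$frac_pop1, 1.0)
  expect_equal(nonsyn$frac_pop3, 1.0)
  # nonsyn-and-nonconservative filter keeps it
  flt <- screen_region(sim$sync, sim$genes, sim$fasta,
                       region = c(core[1], core[2]), nonsyn_only = TRUE)
  expect_equal(flt$pos, nonsyn$pos)
  # region string parsing and the no-polymorphism case
  empty <- screen_region(sim$sync, sim$genes, sim$fasta,
                         region = sprintf("%s:%d-%d", "nochrom", 1, 99))
  expect_equal(nrow(empty), 0L)
  expect_error(screen_region(sim$sync, sim$genes, sim$fasta,
                             region = "badregion"), "bad region")
})

test_that("variant fractions reproduce the truth within binomial error", {
  cfg <- sim_config(genome_length = 50000L, sweep_core = NULL,
                    sweep_extension = NULL, fixed_snp = NULL,
                    theta = 0.02, error_rate = 0, seed = 29L)
  sim <- simulate_pools(cfg)
  sc <- screen_region(sim$sync, sim$genes, sim$fasta, min_count = 1)
  tr <- sim$truth$snps
  merged <- merge(sc[gene_id == "intergenic" | TRUE],
                  tr[, .(pos, alt, freq_pop1)], by = "pos")
  merged <- merged[alt.x == alt.y]
  # binomial read + pool noise at depth ~82: sd ~ sqrt(pq/82) + pool term
  dev <- merged$frac_pop1 - merged$freq_pop1
  expect_lt(mean(abs(dev)), 0.08)
  expect_lt(abs(mean(dev)), 0.01)
})
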