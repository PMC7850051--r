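## data.table non-standard-evaluation column names.
utils::globalVariables(c(
  "type", "valid", "tajD", "covered_frac", "population", "n_windows",
  "genes", "pop_pair", "fst_classical", "fst_anova", "conc", "n_dead",
  "conservative", "consequence", "pos", "chrom", "d2", "p_value",
  "q_value", "fractions", "populations", "start", "end", ".N", ".SD",
  "n", "dead"))
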