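# Independent brute-force oracles, kept deliberately separate from the
# package implementation: translation goes through seqinr, variant
# expansion and resolvability through plain enumeration.

oracle_translate <- function(codon) {
  aa <- seqinr::translate(strsplit(chartr("U", "T", codon), "",
                                   fixed = TRUE)[[1L]])
  paste(aa, collapse = "")
}

oracle_variants <- function(codon) {
  b <- strsplit(codon, "", fixed = TRUE)[[1L]]
  ipos <- which(b == "I")
  combos <- expand.grid(rep(list(c("G", "A", "U")), length(ipos)),
                        stringsAsFactors = FALSE)
  resolved <- apply(combos, 1L, function(repl) {
    bb <- b
    bb[ipos] <- repl
    paste(bb, collapse = "")
  })
  data.frame(resolved_codon = resolved,
             product = vapply(resolved, oracle_translate, character(1),
                              USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

# pairwise-comparison resolvability: product -> how many interpretations
oracle_class_sizes <- function(codon) {
  v <- oracle_variants(codon)
  sort(table(v$product), decreasing = TRUE)
}

oracle_peptide_mass <- function(sequence) {
  # summation over an independently keyed residue table (values as used by
  # proteomics search engines), plus water
  tab <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
           C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
           H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
           M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
           T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
  sum(tab[strsplit(sequence, "", fixed = TRUE)[[1L]]]) + 18.010565
}

# small convenience used across MS tests
norm_and_fractions <- function(sim, params = quant_params()) {
  ref <- sim$species$sequence[sim$species$species_class == "primary"][1L]
  f <- compute_norm_factors(sim$standard1, sim$standard2, reference = ref)
  corrected <- normalize_quant(sim$sample, f)
  list(factors = f, corrected = corrected,
       result = decoding_fractions(corrected, attr(sim$species, "codon"),
                                   params))
}
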