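#' @title In-silico LysC digestion and peptide mass arithmetic
#' @name peptides
NULL

# Monoisotopic residue masses (Da) of the 20 standard amino acids
# (elemental-composition values; peptide mass = sum of residues + water).
AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313)

WATER_MONO <- 18.010565
CARBAMIDOMETHYL <- 57.021464   # fixed modification on Cys
MET_OXIDATION <- 15.994915     # variable modification on Met

#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water. Carbamidomethylation
#' of cysteine is applied as a fixed modification (the standard alkylation
#' in the digestion protocol); methionine oxidation can be added as a
#' variable modification.
#'
#' @param sequence Amino-acid string over the 20 standard one-letter codes.
#'   The empty string returns the mass of water.
#' @param oxidized_met Number of oxidized methionines (default 0; must not
#'   exceed the Met count of the sequence).
#' @param carbamidomethyl Apply +57.021464 Da per cysteine (default TRUE).
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' peptide_mass("G")        # 75.03203
#' peptide_mass("")         # 18.010565 (water)
peptide_mass <- function(sequence, oxidized_met = 0L,
                         carbamidomethyl = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  unknown <- setdiff(aa, names(AA_MONO))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (oxidized_met < 0L || oxidized_met > sum(aa == "M"))
    stop("oxidized_met must be between 0 and the number of Met residues",
         call. = FALSE)
  mass <- sum(AA_MONO[aa]) + WATER_MONO + oxidized_met * MET_OXIDATION
  if (carbamidomethyl) mass <- mass + sum(aa == "C") * CARBAMIDOMETHYL
  unname(mass)
}

#' LysC digestion of a protein
#'
#' Cleaves C-terminally of every lysine (full LysC specificity, no
#' proline block) and returns all peptides with at most `missed_cleavages`
#' internal lysines, in N- to C-terminal order.
#'
#' @param protein Non-empty amino-acid string.
#' @param missed_cleavages Maximum number of internal K residues per
#'   peptide (default 0).
#' @return Character vector of peptides. At 0 missed cleavages the peptides
#'   concatenate back to the input.
#' @export
#' @examples
#' digest_lysC("MDYKDDDDKSSK")  # "MDYK" "DDDDK" "SSK"
digest_lysC <- function(protein, missed_cleavages = 0L) {
  stopifnot(is.character(protein), length(protein) == 1L, !is.na(protein),
            nzchar(protein))
  if (!is.numeric(missed_cleavages) || missed_cleavages < 0)
    stop("missed_cleavages must be a non-negative integer", call. = FALSE)
  missed_cleavages <- as.integer(missed_cleavages)
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  cut_after <- which(aa == "K")
  starts <- c(1L, cut_after[cut_after < length(aa)] + 1L)
  ends <- c(cut_after[cut_after < length(aa)], length(aa))
  base <- substring(protein, starts, ends)
  out <- character(0)
  ord_start <- integer(0)
  for (i in seq_along(base)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > length(base)) break
      out <- c(out, paste0(base[i:j], collapse = ""))
      ord_start <- c(ord_start, starts[i])
    }
  }
  out[order(ord_start, nchar(out))]
}

#' Theoretical peptide species for a test codon
#'
#' Enumerates the peptide species expected in the MS readout of the
#' reporter for a given test codon: the measured LysC peptide (the residues
#' between the two flanking lysines, ending in the C-terminal lysine) in
#' one full-length form per resolvability class, the truncated drop-off
#' product ending at the residue preceding the test codon, and — when the
#' codon has a stop decoding variant — a terminated species (release at the
#' stop; same sequence as the truncated product) plus read-through species
#' for every sense decoding.
#'
#' Full-length species whose masses coincide (Leu/Ile isobars) are merged
#' into one quantification unit with a warning; any remaining pair of
#' full-length species closer than 0.01 Da is flagged `isobaric`.
#'
#' @param test_codon Codon string over `A, C, U, I` (or a plain
#'   `A, C, U, G` control codon).
#' @param backbone Template DNA passed to [build_construct()].
#' @return A data.frame with columns `sequence`, `species_class`
#'   (`primary`, `alternative`, `readthrough`, `terminated`, `truncated`),
#'   `amino_acid` (test-position residue, e.g. `"I/L"` for a merged isobar,
#'   `NA` for truncated/terminated), `origin_interpretation` (inosine
#'   readings giving rise to the species, `/`-separated), and
#'   `monoisotopic_mass`, `isobaric`. Attribute `codon` carries the test
#'   codon.
#' @export
#' @examples
#' expected_peptides("IAC")
expected_peptides <- function(test_codon, backbone = reporter_backbone()) {
  construct <- build_construct(test_codon, backbone = backbone)
  win <- .measured_window(construct)
  orf <- construct$orf
  ti <- construct$test_codon_index
  translate_design <- function(i) {
    cd <- orf[i]
    if (grepl("I", cd, fixed = TRUE)) cd <- chartr("I", "G", cd)
    translate_codon(cd)
  }
  prefix <- paste(vapply(win$window[win$window < ti], translate_design,
                         character(1)), collapse = "")
  suffix <- paste(vapply(c(win$window[win$window > ti], win$k_after),
                         translate_design, character(1)), collapse = "")

  if (inosine_count(test_codon) > 0L) {
    rep_ <- classify_resolvability(test_codon)
    products <- names(rep_$classes)
    origins <- vapply(rep_$classes, paste, character(1), collapse = "/")
    # the primary decoding is the all-G interpretation (I read as G)
    all_g <- paste(rep("G", inosine_count(test_codon)), collapse = "")
    is_primary <- vapply(rep_$classes, function(x) all_g %in% x,
                         logical(1))
  } else {
    products <- translate_codon(test_codon)
    origins <- NA_character_
    is_primary <- TRUE
  }
  # read-through exists only where the primary decoding is itself a stop
  # (designed stop test codons such as UAI/UIA); a stop among the
  # alternative decodings of a sense codon (e.g. IAA read as UAA) is a
  # premature-termination event instead
  primary_is_stop <- any(is_primary & products == STOP_SYMBOL)

  rows <- list()
  for (i in seq_along(products)) {
    p <- products[i]
    if (p == STOP_SYMBOL) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = prefix, species_class = "terminated",
        amino_acid = NA_character_, origin_interpretation = origins[i],
        stringsAsFactors = FALSE)
    } else {
      cls <- if (primary_is_stop) "readthrough"
      else if (is_primary[i]) "primary" else "alternative"
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = paste0(prefix, p, suffix), species_class = cls,
        amino_acid = p, origin_interpretation = origins[i],
        stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    sequence = prefix, species_class = "truncated",
    amino_acid = NA_character_, origin_interpretation = NA_character_,
    stringsAsFactors = FALSE)
  species <- do.call(rbind, rows)
  species$monoisotopic_mass <- vapply(species$sequence, peptide_mass,
                                      numeric(1), USE.NAMES = FALSE)

  # merge full-length species with identical mass (Leu/Ile isobars):
  # MS cannot distinguish them, so they form one quantification unit
  full <- species$species_class %in% c("primary", "alternative",
                                       "readthrough")
  species$isobaric <- FALSE
  fi <- which(full)
  if (length(fi) > 1L) {
    drop <- logical(nrow(species))
    for (a in seq_along(fi)) {
      for (b in seq_along(fi)) {
        if (b <= a) next
        ia <- fi[a]; ib <- fi[b]
        if (drop[ia] || drop[ib]) next
        if (abs(species$monoisotopic_mass[ia] -
                species$monoisotopic_mass[ib]) < 0.01) {
          warning("isobaric full-length species ",
                  species$amino_acid[ia], " and ", species$amino_acid[ib],
                  " for codon ", toupper(test_codon),
                  " merged into one quantification unit", call. = FALSE)
          species$amino_acid[ia] <- paste(species$amino_acid[ia],
                                          species$amino_acid[ib], sep = "/")
          species$origin_interpretation[ia] <-
            paste(species$origin_interpretation[ia],
                  species$origin_interpretation[ib], sep = "/")
          if (species$species_class[ib] == "primary")
            species$species_class[ia] <- "primary"
          species$isobaric[ia] <- TRUE
          drop[ib] <- TRUE
        }
      }
    }
    species <- species[!drop, , drop = FALSE]
  }
  rownames(species) <- NULL
  attr(species, "codon") <- toupper(test_codon)
  species
}
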