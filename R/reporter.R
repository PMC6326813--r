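#' @title Reporter construct for single-codon inosine decoding assays
#'
#' @description
#' The reporter is a short ORF designed so that the only guanosine positions
#' that matter for the mass-spectrometric readout sit in a single test
#' codon. Transcription with ITP in place of GTP puts inosine wherever the
#' template encodes G, so a construct whose measured peptide window is
#' otherwise G-free carries inosine exclusively at the test codon. The ORF
#' encodes a FLAG tag for affinity purification and the test residue is
#' flanked by two lysines, so that LysC digestion releases one peptide
#' containing the test amino acid.
#'
#' @name reporter
NULL

# Template DNA of the reporter (sense strand): T7 promoter, A/C/T-rich
# 5'UTR, ATG, FLAG tag, Leu-Ser-Lys, 8-residue spacer, test codon (NNN),
# Ser-Asn-Ile-Ser-Lys, C-terminal extension, TAA stop, 3'UTR and poly(A).
REPORTER_TEMPLATE <- paste0(
  "TAATACGACTCACTATAGGGTCATACAACATACAAACATACTACACATACAAACACACAATACAACAAC",
  "ATACATACAACAATCTTAATTAACACCACCATGGACTATAAAGACGATGACGATAAACTCTCGAAATCA",
  "TCATTCTACTCCTTAACATCCNNNTCTAACATATCCAAACTAGCCGAATTCATCATAATTTTAAACTAC",
  "ACATTCATCTTATTATTAAACATCTCCACCTATCTATTACTTTCCTTATCATCCTCTTACCCATGCCAC",
  "TAATGATAAGAATTCTAATAACACTATACTATTTCTTACTATCCGGGTACTGCGCAAAAAAAAAAAAAA",
  "AAAAAAAAAAAAAAAAAAAAAAAAAAAGATCT")

T7_PROMOTER <- "TAATACGACTCACTATA"

#' Reporter backbone template
#'
#' Returns the reporter template DNA (sense strand) with the test codon as
#' the placeholder `NNN`.
#'
#' @return A character string (DNA alphabet plus `NNN`).
#' @export
reporter_backbone <- function() REPORTER_TEMPLATE

#' Build a reporter construct for a test codon
#'
#' Substitutes the test codon into the backbone, derives the ITP transcript
#' (every template G transcribed as inosine) and walks the reading frame
#' from the start codon to locate the test codon and the designed stop.
#'
#' The ORF is represented at the design (template) level: codons are read
#' from the template DNA in RNA letters, with the test codon carried exactly
#' as supplied (inosines included). The ITP transcript itself contains no G
#' anywhere — including the start codon, which is physically AUI — but the
#' design-level ORF is the frame the species arithmetic works in.
#'
#' @param test_codon Codon string over `A, C, U, I` (or `A, C, U, G` for
#'   unmodified controls).
#' @param backbone Template DNA with an `NNN` placeholder; defaults to the
#'   shipped reporter backbone.
#' @return An object of class `reporter_construct`: list with
#'   `test_codon`, `template_dna` (NNN substituted), `transcript_rna`
#'   (ITP product, G-free), `orf` (character vector of RNA codons from AUG
#'   to the designed stop, test codon as supplied), `test_codon_index`
#'   (1-based ORF codon index) and `orf_start` (0-based template offset of
#'   the A of AUG).
#' @export
#' @examples
#' rc <- build_construct("IAC")
#' rc$orf[rc$test_codon_index]  # "IAC"
build_construct <- function(test_codon, backbone = reporter_backbone()) {
  test_codon <- .check_codon(test_codon)
  # template-level codon: I is encoded by G (ITP is incorporated opposite
  # template C, i.e. wherever the sense strand says G), U by T
  codon_dna <- chartr("UI", "TG", test_codon)

  nnn <- gregexpr("NNN", backbone, fixed = TRUE)[[1L]]
  if (length(nnn) != 1L || nnn[1L] == -1L)
    stop("backbone integrity failure: expected exactly one NNN placeholder",
         call. = FALSE)
  if (!grepl(T7_PROMOTER, backbone, fixed = TRUE))
    stop("backbone integrity failure: T7 promoter not found", call. = FALSE)
  template <- sub("NNN", codon_dna, backbone, fixed = TRUE)

  atg <- regexpr("ATG", template, fixed = TRUE)
  if (atg == -1L)
    stop("backbone integrity failure: no ATG start codon", call. = FALSE)
  if ((nnn[1L] - atg) %% 3L != 0L || nnn[1L] <= atg)
    stop("backbone integrity failure: test codon not in frame with ATG",
         call. = FALSE)
  test_index <- as.integer((nnn[1L] - atg) %/% 3L + 1L)

  # frame-walk from ATG to the first designed stop codon (the test codon is
  # skipped in the stop check: stop-variant test codons such as UAI must not
  # terminate the designed ORF)
  orf_dna <- substring(template, atg)
  n_codons <- nchar(orf_dna) %/% 3L
  codons <- substring(orf_dna, 3L * seq_len(n_codons) - 2L,
                      3L * seq_len(n_codons))
  codons_rna <- chartr("T", "U", codons)
  stop_at <- NA_integer_
  for (i in seq_len(n_codons)) {
    if (i == test_index) next
    if (translate_codon(codons_rna[i]) == STOP_SYMBOL) { stop_at <- i; break }
  }
  if (is.na(stop_at) || stop_at <= test_index)
    stop("backbone integrity failure: no in-frame stop downstream of the ",
         "test codon", call. = FALSE)
  orf <- codons_rna[seq_len(stop_at)]
  orf[test_index] <- test_codon

  # ITP transcription starts at the +1 G of the promoter; every G is I
  txn_start <- regexpr(T7_PROMOTER, template, fixed = TRUE) +
    nchar(T7_PROMOTER)
  transcript <- chartr("TG", "UI", substring(template, txn_start))

  structure(list(test_codon = test_codon,
                 template_dna = template,
                 transcript_rna = transcript,
                 orf = orf,
                 test_codon_index = test_index,
                 orf_start = as.integer(atg) - 1L),
            class = "reporter_construct")
}

#' @export
print.reporter_construct <- function(x, ...) {
  cat("Reporter construct, test codon ", x$test_codon,
      " at ORF codon ", x$test_codon_index, " of ", length(x$orf),
      "\n", sep = "")
  cat("Template: ", nchar(x$template_dna), " bp; ITP transcript: ",
      nchar(x$transcript_rna), " nt (G-free)\n", sep = "")
  invisible(x)
}

# Measured peptide window: the LysC peptide carrying the test residue.
# Lysine codons are located at the design level (AAA/AAG) on either side of
# the test codon; the window is the codons strictly between them.
.measured_window <- function(construct) {
  orf <- construct$orf
  ti <- construct$test_codon_index
  is_lys <- vapply(seq_along(orf), function(i) {
    if (i == ti) return(FALSE)
    cd <- orf[i]
    if (grepl("I", cd, fixed = TRUE)) cd <- chartr("I", "G", cd)
    translate_codon(cd) == "K"
  }, logical(1))
  k_before <- suppressWarnings(max(which(is_lys & seq_along(orf) < ti)))
  k_after <- suppressWarnings(min(which(is_lys & seq_along(orf) > ti)))
  if (!is.finite(k_before) || !is.finite(k_after))
    stop("no flanking lysine codons around the test codon", call. = FALSE)
  list(k_before = k_before, k_after = k_after,
       window = seq(k_before + 1L, k_after - 1L))
}

#' Validate a reporter construct
#'
#' Reports every G position in the design-level ORF outside the test codon.
#' Under ITP transcription each of these G's becomes an inosine, so each
#' affected codon is classified by whether replacing its G's with I leaves
#' the amino-acid product unchanged under every decoding
#' (`"synonymous"`, e.g. UCG -> UCI, all-Ser) or not (`"non_synonymous"`).
#' A non-test G inside the measured peptide window (the residues strictly
#' between the two lysines flanking the test codon) would corrupt the MS
#' readout and is a hard failure.
#'
#' @param construct A `reporter_construct`.
#' @return An object of class `reporter_validation`: list with `ok`,
#'   `g_codons` (data.frame: codon_index, codon, n_g, classification,
#'   in_measured_window) and `window` (codon indices of the measured
#'   window).
#' @export
validate_construct <- function(construct) {
  stopifnot(inherits(construct, "reporter_construct"))
  win <- .measured_window(construct)
  orf <- construct$orf
  ti <- construct$test_codon_index
  has_g <- grepl("G", orf, fixed = TRUE) & seq_along(orf) != ti
  idx <- which(has_g)
  classify <- function(cd) {
    ref <- translate_codon(cd)
    isub <- chartr("G", "I", cd)
    prods <- decoding_variants(isub)$product
    if (all(prods == ref)) "synonymous" else "non_synonymous"
  }
  g_codons <- data.frame(
    codon_index = idx,
    codon = orf[idx],
    n_g = vapply(strsplit(orf[idx], "", fixed = TRUE),
                 function(b) sum(b == "G"), integer(1)),
    classification = vapply(orf[idx], classify, character(1),
                            USE.NAMES = FALSE),
    in_measured_window = idx %in% win$window,
    stringsAsFactors = FALSE)
  if (any(g_codons$in_measured_window))
    stop("construct invalid: non-test G inside the measured peptide window ",
         "(codon ", paste(g_codons$codon_index[g_codons$in_measured_window],
                          collapse = ", "), ")", call. = FALSE)
  structure(list(ok = TRUE, g_codons = g_codons, window = win$window),
            class = "reporter_validation")
}

#' @export
print.reporter_validation <- function(x, ...) {
  cat("Reporter validation: measured window codons ",
      min(x$window), "-", max(x$window), " are G-free\n", sep = "")
  if (nrow(x$g_codons)) {
    cat(nrow(x$g_codons), "G-containing codon(s) outside the window",
        "(inosine-substituted under ITP):\n")
    print(x$g_codons, row.names = FALSE)
  }
  invisible(x)
}
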