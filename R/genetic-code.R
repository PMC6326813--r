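#' @title Genetic-code engine for inosine-containing codons
#'
#' @description
#' Inosine (I), the deamination product of adenosine, base-pairs with C, A or
#' U during decoding and can therefore be read by the ribosome as G, A or U.
#' These functions expand inosine-containing codons into their decoding
#' variants and classify which decodings are distinguishable at the
#' amino-acid level.
#'
#' Codons are plain 3-character strings over the RNA alphabet `A, C, G, U`
#' plus `I`. Codon positions are 1-based; position 3 is the wobble position.
#' STOP is represented by the distinct symbol `"*"`, never as an amino acid.
#'
#' @name genetic-code
NULL

# Decoding interpretations of inosine, ordered by base-pair stability
# I:C > I:A > I:U, i.e. I read as G, then A, then U. This order fixes all
# deterministic output orderings in the package.
INOSINE_READINGS <- c("G", "A", "U")

STOP_SYMBOL <- "*"

.check_codon <- function(codon, alphabet = c("A", "C", "G", "U", "I")) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon))
    stop("codon must be a single character string", call. = FALSE)
  codon <- toupper(codon)
  if (nchar(codon) != 3L)
    stop("codon must have exactly 3 bases, got '", codon, "'", call. = FALSE)
  bases <- strsplit(codon, "", fixed = TRUE)[[1L]]
  bad <- setdiff(bases, alphabet)
  if (length(bad))
    stop("invalid base(s) ", paste(sQuote(bad), collapse = ", "),
         " in codon '", codon, "' (alphabet ",
         paste(alphabet, collapse = ""), ")", call. = FALSE)
  codon
}

#' Count inosines in a codon
#'
#' @param codon A codon string over `A, C, G, U, I` (vectorized).
#' @return Integer vector: number of `I` symbols per codon.
#' @export
#' @examples
#' inosine_count(c("IAC", "III", "ACU"))
inosine_count <- function(codon) {
  vapply(strsplit(toupper(codon), "", fixed = TRUE),
         function(b) sum(b == "I"), integer(1))
}

#' 1-based positions of inosines in a codon
#'
#' Position 3 is the wobble-facing codon position.
#'
#' @param codon A single codon string.
#' @return Integer vector, subset of `1:3`.
#' @export
inosine_positions <- function(codon) {
  codon <- .check_codon(codon)
  which(strsplit(codon, "", fixed = TRUE)[[1L]] == "I")
}

#' Translate an inosine-free RNA codon
#'
#' Standard genetic code (via [Biostrings::GENETIC_CODE]); stop codons
#' UAA/UAG/UGA return `"*"`.
#'
#' @param codon Codon string(s) over `A, C, G, U` (no inosine).
#' @return Character vector of one-letter amino acids or `"*"`.
#' @export
#' @examples
#' translate_codon(c("AUG", "GAC", "UAA"))
translate_codon <- function(codon) {
  vapply(codon, function(cd) {
    cd <- .check_codon(cd, alphabet = c("A", "C", "G", "U"))
    unname(Biostrings::GENETIC_CODE[[chartr("U", "T", cd)]])
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate all inosine-containing codons
#'
#' All triplets over `A, C, U, I` with at least one inosine: the codon space
#' reachable when transcripts are synthesized from A, C, U and I only, so
#' that inosine stands wherever the template encodes G. There are
#' 4^3 - 3^3 = 37 such codons.
#'
#' @return Character vector of length 37, lexicographically sorted.
#' @export
#' @examples
#' length(enumerate_inosine_codons())  # 37
enumerate_inosine_codons <- function() {
  g <- expand.grid(b1 = c("A", "C", "U", "I"), b2 = c("A", "C", "U", "I"),
                   b3 = c("A", "C", "U", "I"), stringsAsFactors = FALSE)
  codons <- paste0(g$b1, g$b2, g$b3)
  sort(codons[grepl("I", codons, fixed = TRUE)])
}

#' Expand an inosine codon into its decoding variants
#'
#' Each inosine is independently read as G, A or U, giving `3^k` variants for
#' a codon with `k` inosines. Variants are ordered with the first inosine
#' position varying slowest, each cycling through G, A, U (the base-pair
#' stability order).
#'
#' @param codon A codon string containing at least one `I`.
#' @return A data.frame with columns `interpretation` (the replacement bases
#'   for the inosine positions, in order, e.g. `"GA"` for a two-inosine
#'   codon), `resolved_codon` (triplet over `A, C, G, U`) and `product`
#'   (one-letter amino acid or `"*"`).
#' @export
#' @examples
#' decoding_variants("IAC")  # GAC/D, AAC/N, UAC/Y
decoding_variants <- function(codon) {
  codon <- .check_codon(codon)
  ipos <- inosine_positions(codon)
  if (length(ipos) == 0L)
    stop("codon '", codon, "' contains no inosine", call. = FALSE)
  k <- length(ipos)
  # expand.grid varies the first factor fastest; reorder so the first
  # inosine position is the slowest-varying (lexicographic in G, A, U)
  g <- do.call(expand.grid, c(rep(list(seq_along(INOSINE_READINGS)), k),
                              stringsAsFactors = FALSE))
  ord <- do.call(order, as.list(g))
  idx <- as.matrix(g)[ord, , drop = FALSE]
  bases <- strsplit(codon, "", fixed = TRUE)[[1L]]
  resolved <- apply(idx, 1L, function(row) {
    b <- bases
    b[ipos] <- INOSINE_READINGS[row]
    paste0(b, collapse = "")
  })
  interp <- apply(idx, 1L, function(row)
    paste0(INOSINE_READINGS[row], collapse = ""))
  data.frame(interpretation = interp,
             resolved_codon = resolved,
             product = translate_codon(resolved),
             stringsAsFactors = FALSE)
}

#' Classify the resolvability of an inosine codon
#'
#' Groups the decoding interpretations of a codon by their amino-acid
#' product. Because of the degeneracy of the genetic code, different
#' decodings of the same codon may be synonymous (e.g. CAI read as CAG or
#' CAA both give Gln); such decodings cannot be distinguished by the
#' identity of the incorporated amino acid.
#'
#' @param codon A codon string containing at least one `I`.
#' @return An object of class `resolvability_report`: a list with
#'   `codon`, `variants` (the [decoding_variants()] table plus a `class_id`
#'   column), `classes` (named list, product -> interpretations),
#'   `fully_resolvable` (TRUE iff every class is a singleton) and
#'   `ambiguous_pairs` (data.frame of interpretation pairs sharing a
#'   product).
#' @export
#' @examples
#' classify_resolvability("CAI")  # CAG/CAA both Gln: not fully resolvable
classify_resolvability <- function(codon) {
  v <- decoding_variants(codon)
  class_id <- match(v$product, unique(v$product))
  v$class_id <- class_id
  classes <- split(v$interpretation, v$product)[unique(v$product)]
  sizes <- lengths(classes)
  pairs <- do.call(rbind, lapply(classes[sizes > 1L], function(ints) {
    cmb <- utils::combn(ints, 2L)
    data.frame(interpretation_1 = cmb[1L, ], interpretation_2 = cmb[2L, ],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs))
    pairs <- data.frame(interpretation_1 = character(0),
                        interpretation_2 = character(0))
  ambiguous <- pairs
  ambiguous$product <- if (nrow(pairs))
    rep(names(classes[sizes > 1L]),
        vapply(classes[sizes > 1L], function(x) choose(length(x), 2L),
               numeric(1)))
  else character(0)
  rownames(ambiguous) <- NULL
  structure(list(codon = toupper(codon),
                 variants = v,
                 classes = classes,
                 fully_resolvable = all(sizes == 1L),
                 ambiguous_pairs = ambiguous),
            class = "resolvability_report")
}

#' @export
print.resolvability_report <- function(x, ...) {
  cat("Inosine codon ", x$codon, " (", inosine_count(x$codon), " inosine",
      if (inosine_count(x$codon) > 1L) "s", " at position ",
      paste(inosine_positions(x$codon), collapse = ","), ")\n", sep = "")
  for (p in names(x$classes)) {
    cat("  ", if (p == STOP_SYMBOL) "STOP" else p, ": I read as ",
        paste(x$classes[[p]], collapse = " / "), "\n", sep = "")
  }
  cat(if (x$fully_resolvable)
    "All decodings distinguishable at the amino-acid level\n"
    else
      "Some decodings are synonymous (not fully resolvable)\n")
  invisible(x)
}

#' Read-through identities of a stop-variant codon
#'
#' For a codon with at least one decoding variant that is a stop codon,
#' returns the non-stop amino acids among its variants: the residues that
#' would appear in a full-length product if the ribosome read through the
#' stop interpretation (e.g. UAI read as UAU gives Tyr).
#'
#' @param codon A codon string containing at least one `I`.
#' @return Character vector of one-letter amino acids (unique, in variant
#'   order).
#' @export
#' @examples
#' stop_readthrough_products("UAI")  # "Y"
stop_readthrough_products <- function(codon) {
  v <- decoding_variants(codon)
  if (!any(v$product == STOP_SYMBOL))
    stop("codon '", toupper(codon),
         "' has no STOP decoding variant", call. = FALSE)
  unique(v$product[v$product != STOP_SYMBOL])
}
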