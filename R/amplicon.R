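#' @title Positional pileup and fidelity QC of reporter amplicons
#'
#' @description
#' Sequencing of cDNA amplicons from the reporter transcript checks that
#' the polymerase incorporated inosine only at the test codon and nothing
#' else drifted. Reads arrive pre-positioned (each carries its 0-based
#' reference offset); the pileup counts bases per reference position and
#' the mismatch rate per position is `1 - ref_count / depth`.
#'
#' Inosine reverse-transcribes like G (C is incorporated opposite I), so
#' reference positions holding I are compared as G: an error-free inosine
#' construct reads back at 100% fidelity. Because of this identity,
#' misincorporation claims from amplicon data are only informative at
#' A/C/U reference positions.
#'
#' Reference coordinates are 0-based with half-open spans throughout.
#'
#' @name amplicon
NULL

PILEUP_BASES <- c("A", "C", "G", "T", "N")

#' Build a positional pileup from positioned reads
#'
#' @param reads A data.frame with columns `seq` (read sequence, DNA
#'   alphabet as reported by the sequencer) and `offset` (0-based start of
#'   the read on the reference).
#' @param reference Reference sequence; may contain `U` and `I`, which are
#'   compared in sequencer space as `T` and `G`.
#' @return An object of class `pileup`: data.frame with columns `pos`
#'   (0-based), `ref` (sequencer-space reference base), counts `A, C, G,
#'   T, N`, `depth` and `mismatch_rate` (`NA` where depth is 0).
#' @export
build_pileup <- function(reads, reference) {
  stopifnot(is.data.frame(reads), all(c("seq", "offset") %in% names(reads)))
  ref <- chartr("UI", "TG", toupper(reference))
  L <- nchar(ref)
  if (nrow(reads)) {
    lens <- nchar(reads$seq)
    if (any(reads$offset < 0L) || any(reads$offset + lens > L))
      stop("read extends beyond the reference", call. = FALSE)
    chars <- strsplit(toupper(paste(reads$seq, collapse = "")),
                      "", fixed = TRUE)[[1L]]
    pos <- sequence(lens) + rep(reads$offset, lens)  # 1-based ref position
    bi <- match(chars, PILEUP_BASES)
    bi[is.na(bi)] <- 5L  # anything unexpected counts as N
    counts <- matrix(tabulate((pos - 1L) * 5L + bi, nbins = 5L * L),
                     ncol = 5L, byrow = TRUE,
                     dimnames = list(NULL, PILEUP_BASES))
  } else {
    counts <- matrix(0L, nrow = L, ncol = 5L,
                     dimnames = list(NULL, PILEUP_BASES))
  }
  refb <- strsplit(ref, "", fixed = TRUE)[[1L]]
  depth <- rowSums(counts)
  ref_count <- counts[cbind(seq_len(L), match(refb, PILEUP_BASES))]
  out <- data.frame(pos = seq_len(L) - 1L, ref = refb, counts,
                    depth = depth,
                    mismatch_rate = ifelse(depth > 0,
                                           1 - ref_count / depth, NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("pileup", class(out))
  out
}

#' @export
print.pileup <- function(x, ...) {
  cat("Pileup over ", nrow(x), " positions; mean depth ",
      round(mean(x$depth), 1), "; mean mismatch rate ",
      signif(mean(x$mismatch_rate, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Sequencing fidelity over a codon span
#'
#' The fidelity at a codon is the minimum per-position reference-base
#' fraction over its three positions, as a percent: a conservative
#' single-number summary of how faithfully the span reads back.
#'
#' @param pileup A [build_pileup()] result.
#' @param codon_span Integer vector `c(start, end)`: 0-based half-open
#'   span on the reference (a codon spans 3 positions).
#' @return Fidelity in percent.
#' @export
fidelity_at_codon <- function(pileup, codon_span) {
  stopifnot(inherits(pileup, "pileup"), length(codon_span) == 2L,
            codon_span[2L] > codon_span[1L])
  rows <- pileup$pos >= codon_span[1L] & pileup$pos < codon_span[2L]
  x <- pileup[rows, , drop = FALSE]
  if (nrow(x) == 0L)
    stop("codon span outside the reference", call. = FALSE)
  if (any(x$depth == 0))
    stop("zero depth inside the codon span", call. = FALSE)
  100 * min(1 - x$mismatch_rate)
}

#' 0-based reference span of the test codon on the transcript
#'
#' Convenience for pointing [fidelity_at_codon()] at the test codon of a
#' reporter construct: converts the template-level codon index into the
#' transcript coordinate system the amplicon reads live in.
#'
#' @param construct A `reporter_construct`.
#' @return Integer `c(start, end)`, 0-based half-open on the transcript.
#' @export
test_codon_span <- function(construct) {
  stopifnot(inherits(construct, "reporter_construct"))
  txn_start <- regexpr(T7_PROMOTER, construct$template_dna, fixed = TRUE) +
    nchar(T7_PROMOTER) - 1L  # 0-based transcript origin on the template
  orf0 <- construct$orf_start - as.integer(txn_start)
  start <- orf0 + 3L * (construct$test_codon_index - 1L)
  c(start, start + 3L)
}
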