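#' @title Readers and writers for pipeline inputs and outputs
#'
#' @description
#' Plain-text interchange: TSV for quantification tables, pileups, editing
#' sites and CDS annotation; FASTA/FASTQ through Biostrings; bedGraph
#' coverage through rtracklayer. In RNA FASTA output inosine is written as
#' lowercase `i` (documented dialect; standard alphabets have no inosine
#' code) and read back case-insensitively.
#'
#' @name io
NULL

#' @rdname io
#' @param x Table to write (quant table, pileup, sites or CDS data.frame).
#' @param path File path.
#' @export
write_quant_table <- function(x, path) {
  utils::write.table(validate_quant_table(x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_quant_table <- function(path) {
  validate_quant_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname io
#' @export
write_pileup <- function(x, path) {
  stopifnot(inherits(x, "pileup"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_pileup <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(x) <- c("pileup", class(x))
  x
}

#' @rdname io
#' @export
write_sites <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_sites <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "a_count", "g_count")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("sites table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x
}

#' @rdname io
#' @export
write_cds <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_cds <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cds_start", "cds_end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("CDS table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x
}

#' Write reporter sequences as FASTA
#'
#' RNA sequences may contain inosine, written as lowercase `i`.
#'
#' @param sequences Named character vector.
#' @param path File path.
#' @export
write_fasta <- function(sequences, path) {
  seqs <- chartr("I", "i", sequences)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

#' Write / read positioned synthetic reads as FASTQ plus a truth TSV
#'
#' The FASTQ holds the read sequences (constant placeholder qualities, as
#' synthetic reads carry no error-probability information); the true
#' 0-based offsets are written to `<path>.offsets.tsv` alongside.
#'
#' @param reads Data.frame with `read_id`, `seq`, `offset`.
#' @param path FASTQ path.
#' @return `read_fastq_reads` returns the reads data.frame (offsets joined
#'   back from the sidecar table).
#' @export
write_fastq_reads <- function(reads, path) {
  stopifnot(all(c("read_id", "seq", "offset") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  utils::write.table(reads[, c("read_id", "offset")],
                     paste0(path, ".offsets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fastq_reads
#' @export
read_fastq_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  off <- utils::read.delim(paste0(path, ".offsets.tsv"),
                           stringsAsFactors = FALSE)
  reads <- data.frame(read_id = names(x), seq = as.character(x),
                      stringsAsFactors = FALSE)
  reads$offset <- off$offset[match(reads$read_id, off$read_id)]
  if (anyNA(reads$offset))
    stop("offsets sidecar does not cover all reads", call. = FALSE)
  rownames(reads) <- NULL
  reads
}

#' Write / read per-transcript coverage as bedGraph
#'
#' Transcript ids are used as seqnames; runs of equal coverage are merged.
#' bedGraph does not store transcript lengths, so the reader takes them as
#' an argument (e.g. from the CDS table's `length` column) to restore
#' trailing zero coverage.
#'
#' @param tracks Named list of numeric coverage vectors.
#' @param path bedGraph path.
#' @export
write_coverage_bedgraph <- function(tracks, path) {
  runs <- lapply(names(tracks), function(id) {
    r <- S4Vectors::Rle(tracks[[id]])
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    keep <- S4Vectors::runValue(r) != 0
    data.frame(seqnames = id, start = starts[keep], end = ends[keep],
               score = S4Vectors::runValue(r)[keep],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, runs)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_coverage_bedgraph
#' @param lengths Named integer vector of transcript lengths.
#' @export
read_coverage_bedgraph <- function(path, lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- lapply(names(lengths), function(id) {
    v <- numeric(lengths[[id]])
    sub <- gr[GenomicRanges::seqnames(gr) == id]
    if (length(sub)) {
      s <- GenomicRanges::start(sub)
      e <- GenomicRanges::end(sub)
      for (i in seq_along(sub)) v[s[i]:e[i]] <- sub$score[i]
    }
    v
  })
  names(out) <- names(lengths)
  out
}
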