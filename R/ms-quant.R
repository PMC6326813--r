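#' @title Concatemer-normalized decoding fractions and truncation rates
#'
#' @description
#' Peak intensities of different peptides do not reflect their molar
#' amounts: each peptide has its own MS response. The pipeline calibrates
#' per-peptide response factors from two concatemer standards — fusion
#' proteins carrying every candidate peptide once, in two different orders,
#' hence equimolar by construction — and divides sample intensities by
#' these factors before computing decoding fractions, truncation
#' percentages and stop read-through.
#'
#' A quantification table is a data.frame with columns `sample_id`,
#' `codon`, `peptide`, `species_class` and `intensity` (non-negative; at
#' most one row per sample and peptide).
#'
#' @name ms-quant
NULL

FULL_LENGTH_CLASSES <- c("primary", "alternative")

#' Construct / validate a quantification table
#'
#' @param sample_id,codon,peptide,species_class,intensity Column vectors
#'   (recycled to a common length).
#' @return A validated data.frame of class `quant_table`.
#' @export
quant_table <- function(sample_id, codon, peptide, species_class,
                        intensity) {
  x <- data.frame(sample_id = as.character(sample_id),
                  codon = toupper(as.character(codon)),
                  peptide = as.character(peptide),
                  species_class = as.character(species_class),
                  intensity = as.numeric(intensity),
                  stringsAsFactors = FALSE)
  validate_quant_table(x)
}

#' @rdname quant_table
#' @param x A data.frame with the quantification-table columns.
#' @export
validate_quant_table <- function(x) {
  need <- c("sample_id", "codon", "peptide", "species_class", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("quant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x$intensity)) || any(x$intensity < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  if (anyDuplicated(x[, c("sample_id", "peptide")]))
    stop("at most one row per (sample_id, peptide) is allowed",
         call. = FALSE)
  class(x) <- unique(c("quant_table", class(x)))
  x
}

#' Analysis parameters for MS quantification
#'
#' @param alt_threshold Detection threshold for alternative decoding, in
#'   percent of the total full-length signal (default 0.4).
#' @param truncation_threshold Truncation percentages at or below this
#'   value are reported as 0 (default 0.4).
#' @param digits Rounding granularity for group summaries (default 2
#'   decimals).
#' @return A list of class `quant_params`.
#' @export
quant_params <- function(alt_threshold = 0.4, truncation_threshold = 0.4,
                         digits = 2L) {
  stopifnot(alt_threshold > 0, alt_threshold < 100,
            truncation_threshold >= 0, truncation_threshold < 100)
  structure(list(alt_threshold = alt_threshold,
                 truncation_threshold = truncation_threshold,
                 digits = as.integer(digits)),
            class = "quant_params")
}

# single intensity per peptide from one standard table; replicate
# injections of the same standard are averaged
.standard_intensity <- function(std, label) {
  v <- validate_quant_table(std)
  tapply(v$intensity, v$peptide, mean)
}

#' Per-peptide response factors from the two concatemer standards
#'
#' In each standard every peptide is equimolar, so the intensity ratio of a
#' peptide to the reference peptide is its relative response factor. The
#' combined factor is the arithmetic mean of the two per-standard factors.
#' Replicate injections of a standard (multiple `sample_id`s) are averaged
#' before forming ratios.
#'
#' @param standard1,standard2 Quantification tables of the two concatemer
#'   standards; every peptide must be present in both with positive
#'   intensity.
#' @param reference Reference peptide sequence (factor fixed at 1);
#'   conventionally the primary (I as G) species.
#' @return A data.frame of class `norm_factors` with columns `peptide`,
#'   `factor_standard1`, `factor_standard2`, `factor`; attribute
#'   `reference`.
#' @export
#' @examples
#' s1 <- quant_table("std1", "IAA", c("PEPK", "PEPE"), "primary", c(2, 1))
#' s2 <- quant_table("std2", "IAA", c("PEPK", "PEPE"), "primary", c(2, 1))
#' compute_norm_factors(s1, s2, reference = "PEPE")
compute_norm_factors <- function(standard1, standard2, reference) {
  i1 <- .standard_intensity(standard1)
  i2 <- .standard_intensity(standard2)
  peptides <- union(names(i1), names(i2))
  missing1 <- setdiff(peptides, names(i1))
  missing2 <- setdiff(peptides, names(i2))
  if (length(missing1) || length(missing2))
    stop("peptide(s) missing from a standard: ",
         paste(unique(c(missing1, missing2)), collapse = ", "),
         call. = FALSE)
  if (!reference %in% peptides)
    stop("reference peptide '", reference, "' not in the standards",
         call. = FALSE)
  if (i1[[reference]] <= 0 || i2[[reference]] <= 0)
    stop("reference peptide has zero intensity in a standard",
         call. = FALSE)
  if (any(i1[peptides] <= 0) || any(i2[peptides] <= 0))
    stop("all standard intensities must be positive", call. = FALSE)
  f1 <- unname(i1[peptides] / i1[[reference]])
  f2 <- unname(i2[peptides] / i2[[reference]])
  out <- data.frame(peptide = peptides,
                    factor_standard1 = f1,
                    factor_standard2 = f2,
                    factor = (f1 + f2) / 2,
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- reference
  class(out) <- c("norm_factors", class(out))
  out
}

#' Apply response-factor normalization to a sample table
#'
#' Divides each raw intensity by the peptide's combined response factor.
#'
#' @param sample A quantification table of in-vitro-translation
#'   measurements.
#' @param factors A `norm_factors` object covering every peptide in
#'   `sample`.
#' @return The table with `intensity` replaced by the corrected intensity
#'   and the input intensities kept in `raw_intensity`.
#' @export
normalize_quant <- function(sample, factors) {
  sample <- validate_quant_table(sample)
  idx <- match(sample$peptide, factors$peptide)
  if (anyNA(idx))
    stop("no normalization factor for peptide(s): ",
         paste(unique(sample$peptide[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  sample$raw_intensity <- sample$intensity
  sample$intensity <- sample$intensity / factors$factor[idx]
  sample
}

#' Decoding fractions of a test codon
#'
#' For each replicate (`sample_id`) the corrected intensity of every
#' full-length species (primary + alternative) is expressed as a percent of
#' their sum; replicates are then combined by averaging the per-replicate
#' fractions (never by pooling intensities), with the s.e.m. across
#' replicates reported. Classes at or below the detection threshold are
#' flagged not-detected but stay in the denominator: the threshold is a
#' detection call, not a censoring of mass.
#'
#' @param corrected A normalized quantification table (see
#'   [normalize_quant()]).
#' @param codon Test codon to summarize.
#' @param params A [quant_params()] object.
#' @return An object of class `decoding_result`: list with `codon`,
#'   `fractions` (data.frame: peptide, species_class, percent, sem,
#'   detected), `inosine_count`, `inosine_positions`, `n_replicates`,
#'   `params`.
#' @export
decoding_fractions <- function(corrected, codon, params = quant_params()) {
  corrected <- validate_quant_table(corrected)
  codon <- toupper(codon)
  x <- corrected[corrected$codon == codon &
                   corrected$species_class %in% FULL_LENGTH_CLASSES, ,
                 drop = FALSE]
  if (nrow(x) == 0L)
    stop("no full-length species quantified for codon ", codon,
         call. = FALSE)
  peptides <- unique(x[, c("peptide", "species_class")])
  reps <- unique(x$sample_id)
  frac <- sapply(reps, function(r) {
    xr <- x[x$sample_id == r, , drop = FALSE]
    v <- xr$intensity[match(peptides$peptide, xr$peptide)]
    v[is.na(v)] <- 0
    tot <- sum(v)
    if (tot <= 0)
      stop("all full-length intensities are zero in replicate ", r,
           call. = FALSE)
    100 * v / tot
  })
  frac <- matrix(frac, nrow = nrow(peptides))
  percent <- rowMeans(frac)
  sem <- if (ncol(frac) > 1L)
    apply(frac, 1L, stats::sd) / sqrt(ncol(frac)) else rep(NA_real_,
                                                           nrow(frac))
  out <- data.frame(peptide = peptides$peptide,
                    species_class = peptides$species_class,
                    percent = percent, sem = sem,
                    detected = percent > params$alt_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent), , drop = FALSE]
  rownames(out) <- NULL
  ic <- if (grepl("I", codon, fixed = TRUE)) inosine_count(codon) else 0L
  structure(list(codon = codon, fractions = out,
                 inosine_count = ic,
                 inosine_positions = if (ic > 0L)
                   inosine_positions(codon) else integer(0),
                 n_replicates = length(reps), params = params),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("Decoding of ", x$codon, " (", x$n_replicates, " replicate",
      if (x$n_replicates > 1L) "s", ")\n", sep = "")
  df <- x$fractions
  df$percent <- round(df$percent, 2L)
  df$sem <- round(df$sem, 2L)
  print(df, row.names = FALSE)
  invisible(x)
}

# shared replicate-averaged ratio: 100 * num / (num + denom) per replicate
.replicate_percent <- function(tab, num_classes, denom_classes, codon,
                               what) {
  x <- tab[tab$codon == codon, , drop = FALSE]
  num <- x[x$species_class %in% num_classes, , drop = FALSE]
  den <- x[x$species_class %in% denom_classes, , drop = FALSE]
  if (nrow(num) == 0L || nrow(den) == 0L)
    stop("codon ", codon, ": both ", what,
         " and reference species rows are required", call. = FALSE)
  reps <- unique(x$sample_id)
  vals <- vapply(reps, function(r) {
    n <- sum(num$intensity[num$sample_id == r])
    d <- sum(den$intensity[den$sample_id == r])
    if (n + d <= 0)
      stop("codon ", codon, ", replicate ", r,
           ": zero denominator", call. = FALSE)
    100 * n / (n + d)
  }, numeric(1))
  res <- mean(vals)
  attr(res, "sem") <- if (length(vals) > 1L)
    stats::sd(vals) / sqrt(length(vals)) else NA_real_
  res
}

#' Truncation percentage of a test codon
#'
#' Ribosome drop-off at the test codon yields a peptide truncated
#' immediately upstream of the test position. The truncation percentage is
#' `100 * truncated / (truncated + sum of full-length species)`, computed
#' per replicate and averaged; values at or below the detection threshold
#' are reported as 0.
#'
#' @inheritParams decoding_fractions
#' @return Numeric percentage (attribute `sem`: s.e.m. across replicates).
#' @export
truncation_percent <- function(corrected, codon, params = quant_params()) {
  corrected <- validate_quant_table(corrected)
  res <- .replicate_percent(corrected, "truncated", FULL_LENGTH_CLASSES,
                            toupper(codon), "truncated")
  if (res <= params$truncation_threshold) {
    sem <- attr(res, "sem")
    res <- 0
    attr(res, "sem") <- sem
  }
  res
}

#' Stop-codon read-through percentage
#'
#' For a stop-variant test codon: `100 * readthrough / (readthrough +
#' terminated)`, per replicate, averaged.
#'
#' @inheritParams decoding_fractions
#' @return Numeric percentage (attribute `sem`).
#' @export
readthrough_percent <- function(corrected, codon) {
  corrected <- validate_quant_table(corrected)
  .replicate_percent(corrected, "readthrough", "terminated",
                     toupper(codon), "readthrough")
}

#' Group truncation percentages by inosine content
#'
#' Unweighted arithmetic mean of per-codon truncation percentages, grouped
#' either by the number of inosines in the codon or by the position of the
#' single inosine (single-inosine codons only).
#'
#' @param results A data.frame with columns `codon` and
#'   `truncation_percent` (one row per codon), e.g. the bundled measured
#'   table from [load_truncation_table()].
#' @param by `"inosine_count"` or `"single_inosine_position"`.
#' @param params A [quant_params()] object (controls rounding of the
#'   reported means).
#' @return A data.frame with columns `group`, `n`, `mean_truncation`,
#'   `sem`.
#' @export
#' @examples
#' tb <- load_truncation_table()
#' group_truncation(tb, by = "inosine_count")
group_truncation <- function(results,
                             by = c("inosine_count",
                                    "single_inosine_position"),
                             params = quant_params()) {
  by <- match.arg(by)
  stopifnot(is.data.frame(results),
            all(c("codon", "truncation_percent") %in% names(results)))
  if (nrow(results) == 0L) stop("no codons to group", call. = FALSE)
  x <- results
  x$codon <- toupper(x$codon)
  counts <- inosine_count(x$codon)
  if (by == "inosine_count") {
    x$group <- counts
    levels_all <- sort(unique(counts[counts > 0L]))
    x <- x[counts > 0L, , drop = FALSE]
  } else {
    keep <- counts == 1L
    if (!all(keep))
      x <- x[keep, , drop = FALSE]
    x$group <- vapply(x$codon, function(cd) inosine_positions(cd),
                      integer(1))
    levels_all <- 1:3
  }
  empty <- setdiff(levels_all, unique(x$group))
  if (length(empty))
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "),
            call. = FALSE)
  agg <- lapply(split(x$truncation_percent, x$group), function(v) {
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else
        NA_real_)
  })
  out <- data.frame(group = as.integer(names(agg)),
                    n = vapply(agg, `[[`, numeric(1), "n"),
                    mean_truncation = round(
                      vapply(agg, `[[`, numeric(1), "mean"),
                      params$digits),
                    sem = round(vapply(agg, `[[`, numeric(1), "sem"),
                                params$digits))
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

#' Measured per-codon truncation percentages
#'
#' Loads the bundled table of truncation percentages measured by the
#' reporter MS assay for the 31 inosine-containing sense test codons
#' (truncation at or below the 0.4% detection threshold recorded as 0).
#'
#' @return A data.frame with columns `codon`, `truncation_percent` and the
#'   derived `inosine_count` and `inosine_position` (position of the single
#'   inosine, NA for multi-inosine codons).
#' @export
load_truncation_table <- function() {
  path <- system.file("extdata", "truncation_table.tsv",
                      package = "inodecode", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$inosine_count <- inosine_count(x$codon)
  x$inosine_position <- ifelse(
    x$inosine_count == 1L,
    vapply(x$codon, function(cd) inosine_positions(cd)[1L], integer(1)),
    NA_integer_)
  x
}
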