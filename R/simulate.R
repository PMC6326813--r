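#' @title Seeded synthetic-data generators
#'
#' @description
#' Generators producing every input the pipeline consumes, with the
#' statistical structure the analysis assumes: MS intensity tables with
#' per-peptide detectability bias (log-normal response factors) and
#' multiplicative log-normal noise; amplicon reads with a uniform per-base
#' substitution error; ribosome-profiling coverage with a configurable
#' stalling signature and mRNA-seq base counts with binomial sampling of
#' the editing rate. Every generator is a pure function of its arguments
#' and seed: fixed seed, identical output. Truth values are always
#' returned alongside, for parameter-recovery tests.
#'
#' @name synthetic-data
NULL

.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
}

#' Simulate an MS quantification dataset for one test codon
#'
#' Builds the expected peptide species of the codon, assigns true
#' abundances (`truncation` to the truncated species, the rest split over
#' the full-length/read-through species by `fractions`), draws per-peptide
#' response factors and emits the in-vitro-translation sample table plus
#' the two concatemer standard tables (equimolar peptides times response
#' factor times noise).
#'
#' @param codon Test codon.
#' @param fractions Named numeric vector over the `amino_acid` labels of
#'   the codon's full-length species (plus `"terminated"` for designed
#'   stop test codons, whose accurate-termination product is quantified
#'   explicitly); must sum to 1.
#' @param truncation True truncated fraction of total product (default 0).
#' @param n_replicates Translation replicates (default 3).
#' @param cv Multiplicative noise CV on every measured intensity
#'   (default 0.1).
#' @param response_sigma sdlog of the log-normal per-peptide response
#'   factors around 1 (default 0.3). Ignored for peptides named in
#'   `response_factors`.
#' @param response_factors Optional named numeric vector (by `amino_acid`
#'   label) forcing true response factors for specific species.
#' @param n_standard_replicates Replicate injections per concatemer
#'   standard (default 3); [compute_norm_factors()] averages them.
#' @param total_abundance Total molar signal scale (default 1e6).
#' @param seed Integer seed.
#' @return List with `sample`, `standard1`, `standard2` (quant tables),
#'   `species` (the [expected_peptides()] table) and `truth` (list:
#'   `fractions`, `truncation`, `response_factors` named by peptide).
#' @export
sim_ms_dataset <- function(codon, fractions, truncation = 0,
                           n_replicates = 3L, cv = 0.1,
                           response_sigma = 0.3, response_factors = NULL,
                           n_standard_replicates = 3L,
                           total_abundance = 1e6, seed = 1L) {
  set.seed(seed)
  species <- suppressWarnings(expected_peptides(codon))
  # drop-off and termination products are the same molecule; quantify once:
  # stop-codon assays keep the terminated species, sense-codon assays fold
  # any premature-termination product into the truncated species
  if (any(species$species_class == "readthrough"))
    species <- species[species$species_class != "truncated", , drop = FALSE]
  else
    species <- species[species$species_class != "terminated", ,
                       drop = FALSE]
  label <- ifelse(is.na(species$amino_acid), species$species_class,
                  species$amino_acid)
  quantified <- species$species_class != "truncated" |
    label == "truncated"
  frac_lab <- setdiff(label, c("truncated"))
  if (!setequal(names(fractions), frac_lab))
    stop("fractions must be named over: ",
         paste(frac_lab, collapse = ", "), call. = FALSE)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  abundance <- ifelse(label == "truncated", truncation,
                      (1 - truncation) * fractions[label])
  if (truncation < 0 || truncation > 1)
    stop("truncation must be in [0, 1]", call. = FALSE)

  n_pep <- nrow(species)
  rf <- stats::rlnorm(n_pep, meanlog = 0, sdlog = response_sigma)
  names(rf) <- species$sequence
  if (!is.null(response_factors)) {
    idx <- match(names(response_factors), label)
    if (anyNA(idx))
      stop("response_factors names not among species labels", call. = FALSE)
    rf[idx] <- response_factors
  }

  mk <- function(ids, abund) {
    do.call(rbind, lapply(ids, function(id) {
      data.frame(sample_id = id, codon = toupper(codon),
                 peptide = species$sequence,
                 species_class = species$species_class,
                 intensity = abund * rf * .lognoise(n_pep, cv),
                 stringsAsFactors = FALSE)
    }))
  }
  sample <- mk(paste0("rep", seq_len(n_replicates)),
               total_abundance * abundance)
  std1 <- mk(paste0("std1_inj", seq_len(n_standard_replicates)),
             total_abundance / n_pep)
  std2 <- mk(paste0("std2_inj", seq_len(n_standard_replicates)),
             total_abundance / n_pep)
  list(sample = validate_quant_table(sample),
       standard1 = validate_quant_table(std1),
       standard2 = validate_quant_table(std2),
       species = species,
       truth = list(fractions = fractions, truncation = truncation,
                    response_factors = rf))
}

#' Simulate positioned amplicon reads from a transcript
#'
#' Reads are sampled uniformly along the reference with i.i.d. per-base
#' substitution errors; inosine is emitted as G (the sequencer cannot tell
#' them apart).
#'
#' @param transcript Reference sequence (RNA with I allowed).
#' @param n_reads Number of reads (default 100).
#' @param read_length Read length (default 100; must not exceed the
#'   reference).
#' @param error_rate Per-base substitution probability in `[0, 1)`
#'   (default 0.002).
#' @param seed Integer seed.
#' @return List with `reads` (data.frame: `read_id`, `seq`, `offset`),
#'   `reference` (sequencer-space DNA) and `error_rate`.
#' @export
sim_amplicon_reads <- function(transcript, n_reads = 100L,
                               read_length = 100L, error_rate = 0.002,
                               seed = 1L) {
  set.seed(seed)
  stopifnot(error_rate >= 0, error_rate < 1)
  ref <- chartr("UI", "TG", toupper(transcript))
  L <- nchar(ref)
  if (read_length > L)
    stop("read_length exceeds the reference length", call. = FALSE)
  offsets <- sample.int(L - read_length + 1L, n_reads, replace = TRUE) - 1L
  seqs <- substring(ref, offsets + 1L, offsets + read_length)
  if (error_rate > 0) {
    chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(chars)) < error_rate)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      repl <- vapply(chars[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      chars[hit] <- repl
      seqs <- vapply(seq_len(n_reads), function(i) {
        paste(chars[((i - 1L) * read_length + 1L):(i * read_length)],
              collapse = "")
      }, character(1))
    }
  }
  list(reads = data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
                          seq = seqs, offset = offsets,
                          stringsAsFactors = FALSE),
       reference = ref, error_rate = error_rate)
}

#' Simulate a ribosome-profiling + mRNA-seq dataset
#'
#' One editing site per transcript. Coverage is Poisson with mean
#' `mean_coverage`; at edited sites the Poisson mean over the site's codon
#' plus one codon on either side (9 nt) is scaled by
#' `1 - rate * (1 - dip)`, i.e. the fully edited molecules are covered at
#' `dip` times baseline while unedited molecules are unaffected. An
#' optional exponential queueing bump can be added upstream (off by
#' default so the null stays clean). mRNA-seq A/G counts are binomial at
#' the true editing rate.
#'
#' @param n_transcripts Number of transcripts (default 100).
#' @param transcript_length Transcript length in nt (default 3000).
#' @param mean_coverage Poisson mean per nt (default 5).
#' @param dip Stall dip factor `d` in `[0, 1]`: relative coverage of a
#'   fully edited molecule at the site (1 = no stall; default 1).
#' @param editing_rates Either a single value in `[0, 1]` used for all
#'   edited transcripts, or `c(alpha, beta)` of a Beta distribution to
#'   draw per-site rates from (default `c(2, 2)`).
#' @param prop_edited Fraction of transcripts whose site is edited
#'   (default 0.5; the rest have true rate 0).
#' @param mrna_depth Informative mRNA-seq reads per site (default 100).
#' @param queue_amplitude,queue_extent Optional upstream queueing bump:
#'   Poisson mean multiplied by `1 + rate * queue_amplitude *
#'   exp(-(distance) / queue_extent)` for positions upstream of the site
#'   (default amplitude 0 = off).
#' @param cds_margin CDS starts at this offset and ends this far from the
#'   transcript end (default 150 nt).
#' @param seed Integer seed.
#' @return List with `tracks` (named list of coverage vectors), `sites`
#'   (data.frame: `transcript_id`, `position`, `a_count`, `g_count`,
#'   `true_rate`), `cds` (data.frame: `transcript_id`, `cds_start`,
#'   `cds_end`, `length`) and `dip`.
#' @export
sim_ribo_dataset <- function(n_transcripts = 100L,
                             transcript_length = 3000L, mean_coverage = 5,
                             dip = 1, editing_rates = c(2, 2),
                             prop_edited = 0.5, mrna_depth = 100L,
                             queue_amplitude = 0, queue_extent = 150,
                             cds_margin = 150L, seed = 1L) {
  set.seed(seed)
  stopifnot(dip >= 0, dip <= 1, prop_edited >= 0, prop_edited <= 1,
            transcript_length > 2L * cds_margin + 100L)
  ids <- sprintf("tx%04d", seq_len(n_transcripts))
  L <- transcript_length
  cds_start <- cds_margin
  cds_end <- L - cds_margin
  n_edited <- round(prop_edited * n_transcripts)
  edited <- seq_len(n_transcripts) <= n_edited
  rate <- numeric(n_transcripts)
  if (n_edited > 0) {
    rate[edited] <- if (length(editing_rates) == 1L)
      rep(editing_rates, n_edited)
    else stats::rbeta(n_edited, editing_rates[1L], editing_rates[2L])
  }
  # keep the site away from transcript ends so +/-1000 nt windows fit on
  # average; position drawn uniformly => codon positions are uniform
  pos <- cds_start + sample.int(cds_end - cds_start - 6L, n_transcripts,
                                replace = TRUE) + 2L
  tracks <- vector("list", n_transcripts)
  names(tracks) <- ids
  for (i in seq_len(n_transcripts)) {
    lambda <- rep(mean_coverage, L)
    p1 <- pos[i] + 1L
    # stall: the codon containing the site plus one codon on either side
    frame_off <- (pos[i] - cds_start) %% 3L
    dip_start <- max(1L, p1 - frame_off - 3L)
    dip_end <- min(L, p1 - frame_off + 5L)
    lambda[dip_start:dip_end] <- lambda[dip_start:dip_end] *
      (1 - rate[i] * (1 - dip))
    if (queue_amplitude > 0 && rate[i] > 0) {
      up <- seq_len(max(0L, dip_start - 1L))
      dist <- dip_start - up
      lambda[up] <- lambda[up] *
        (1 + rate[i] * queue_amplitude * exp(-dist / queue_extent))
    }
    tracks[[i]] <- stats::rpois(L, lambda)
  }
  g <- stats::rbinom(n_transcripts, mrna_depth, rate)
  sites <- data.frame(transcript_id = ids, position = pos,
                      a_count = mrna_depth - g, g_count = g,
                      true_rate = rate, stringsAsFactors = FALSE)
  cds <- data.frame(transcript_id = ids, cds_start = cds_start,
                    cds_end = cds_end, length = L,
                    stringsAsFactors = FALSE)
  list(tracks = tracks, sites = sites, cds = cds, dip = dip)
}
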