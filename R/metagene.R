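#' @title Editing-rate-weighted metagene analysis of ribosome profiling
#'
#' @description
#' If inosine slows the ribosome, ribosome-profiling coverage should dip at
#' edited positions. The metagene analysis aligns per-transcript coverage
#' windows on A-to-I editing sites, normalizes each window by its total
#' signal, weights edited sites by their mRNA-seq editing rate (so highly
#' edited sites carry more signal) and averages.
#'
#' Coverage tracks are named numeric vectors (one per transcript,
#' position 1 = transcript nucleotide 0). Editing sites carry 0-based
#' transcript positions and mRNA-seq A/G counts. All transcript coordinates
#' are 0-based, half-open.
#'
#' @name ribo-metagene
NULL

#' Metagene analysis parameters
#'
#' @param norm_window Half-width of the normalization window in nt: each
#'   site's coverage is divided by the total signal within +/- this range
#'   (default 500; the codon-position-split analysis uses 1000).
#' @param display_window Half-width of the reported profile in nt
#'   (default 125).
#' @param neighbor_radius Transcripts with two or more editing sites within
#'   this distance (nt) of each other are excluded (default 5).
#' @param weighting `"editing_rate"` (weighted mean, weights = editing
#'   rate, normalized by the sum of weights so a rate-0 site is a no-op) or
#'   `"unweighted"` (plain mean; the mode used for unedited control sites).
#' @param min_reads Minimum informative mRNA-seq reads (A+G) for a site's
#'   editing rate to be trusted (default 10); shallower sites are dropped.
#' @return A list of class `metagene_params`.
#' @export
metagene_params <- function(norm_window = 500L, display_window = 125L,
                            neighbor_radius = 5L,
                            weighting = c("editing_rate", "unweighted"),
                            min_reads = 10L) {
  stopifnot(norm_window >= 1L, display_window >= 1L, neighbor_radius >= 0L)
  structure(list(norm_window = as.integer(norm_window),
                 display_window = as.integer(display_window),
                 neighbor_radius = as.integer(neighbor_radius),
                 weighting = match.arg(weighting),
                 min_reads = as.integer(min_reads)),
            class = "metagene_params")
}

#' A-to-I editing rate from mRNA-seq base counts
#'
#' At a genomically-A position, reads showing G report editing:
#' `rate = g / (a + g)`.
#'
#' @param a_count,g_count Non-negative integer vectors.
#' @return Numeric vector in `[0, 1]`; `NA` where `a + g == 0` (no
#'   informative reads; such sites are dropped downstream).
#' @export
#' @examples
#' editing_rate(80, 20)  # 0.2
editing_rate <- function(a_count, g_count) {
  stopifnot(all(a_count >= 0), all(g_count >= 0))
  tot <- a_count + g_count
  ifelse(tot > 0, g_count / tot, NA_real_)
}

#' Annotate editing sites with rate, status and codon position
#'
#' Computes the editing rate, drops sites without enough informative reads,
#' classifies each site as `edited` (any edited read observed, rate > 0) or
#' `unedited`, resolves each site to one CDS (longest, ties broken by
#' transcript id) and assigns the codon position of the edited nucleotide.
#'
#' @param sites Data.frame with columns `transcript_id`, `position`
#'   (0-based), `a_count`, `g_count`.
#' @param cds Data.frame with columns `transcript_id`, `cds_start`,
#'   `cds_end` (0-based half-open) and optionally `length`.
#' @param params A [metagene_params()] object (`min_reads` guard).
#' @return The sites table with added `editing_rate`, `status` and
#'   `codon_position` (`NA` outside the CDS); under-covered sites removed.
#' @export
annotate_sites <- function(sites, cds, params = metagene_params()) {
  stopifnot(all(c("transcript_id", "position", "a_count", "g_count") %in%
                  names(sites)),
            all(c("transcript_id", "cds_start", "cds_end") %in% names(cds)))
  sites$editing_rate <- editing_rate(sites$a_count, sites$g_count)
  depth <- sites$a_count + sites$g_count
  drop <- is.na(sites$editing_rate) | depth < params$min_reads
  if (any(drop))
    message(sum(drop), " site(s) dropped: fewer than ", params$min_reads,
            " informative mRNA-seq reads")
  sites <- sites[!drop, , drop = FALSE]
  sites$status <- ifelse(sites$editing_rate > 0, "edited", "unedited")
  sites$codon_position <- NA_integer_
  for (i in seq_len(nrow(sites))) {
    cand <- cds[cds$transcript_id == sites$transcript_id[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    sel <- select_cds(cand)
    sites$codon_position[i] <- codon_position(sites$position[i],
                                              sel$cds_start, sel$cds_end)
  }
  rownames(sites) <- NULL
  sites
}

#' Exclude transcripts with clustered editing sites
#'
#' An edited site next to another (edited or not) would contaminate the
#' aligned window, so a transcript is excluded when any two of its sites
#' lie within `radius` nt of each other.
#'
#' @param sites Annotated sites table.
#' @param radius Exclusion radius in nt (default 5): pairs at distance
#'   `<= radius` trigger exclusion; distance `radius + 1` is retained.
#' @return The sites table restricted to retained transcripts.
#' @export
#' @examples
#' s <- data.frame(transcript_id = c("t1", "t1", "t2"),
#'                 position = c(100, 104, 50))
#' filter_neighbor_sites(s)  # t1 excluded (distance 4 <= 5)
filter_neighbor_sites <- function(sites, radius = 5L) {
  stopifnot(all(c("transcript_id", "position") %in% names(sites)))
  bad <- vapply(split(sites$position, sites$transcript_id), function(p) {
    length(p) > 1L && min(diff(sort(p))) <= radius
  }, logical(1))
  keep <- !sites$transcript_id %in% names(bad)[bad]
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select one CDS among several candidates
#'
#' The longest CDS wins; ties are broken lexicographically by transcript
#' id so the choice is deterministic.
#'
#' @param candidates Data.frame with columns `transcript_id`, `cds_start`,
#'   `cds_end`.
#' @return The selected row.
#' @export
select_cds <- function(candidates) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L)
  len <- candidates$cds_end - candidates$cds_start
  ord <- order(-len, candidates$transcript_id)
  candidates[ord[1L], , drop = FALSE]
}

#' Codon position of a transcript coordinate
#'
#' @param position 0-based transcript position of the site.
#' @param cds_start,cds_end 0-based half-open CDS span.
#' @return 1, 2 or 3 (1 = first codon position); `NA` outside the CDS.
#' @export
#' @examples
#' codon_position(14, 10, 100)  # 2
codon_position <- function(position, cds_start, cds_end = Inf) {
  ifelse(position >= cds_start & position < cds_end,
         1L + (position - cds_start) %% 3L, NA_integer_)
}

#' Window-normalized coverage around one site
#'
#' Extracts coverage at relative positions `-display_window .. +
#' display_window` around the site and divides by the total signal within
#' `+/- norm_window`. Positions outside the transcript are masked (`NA`,
#' not zero): zero-filling would fabricate a dip at transcript edges.
#'
#' @param track Numeric coverage vector of the transcript.
#' @param site_position 0-based site position.
#' @param params A [metagene_params()] object.
#' @return Named numeric vector over relative positions, or `NULL` when
#'   the normalization window holds no signal (site dropped upstream with
#'   a log message).
#' @export
normalize_site_window <- function(track, site_position,
                                  params = metagene_params()) {
  L <- length(track)
  stopifnot(site_position >= 0L, site_position < L)
  p1 <- site_position + 1L  # 1-based index of the site
  wn <- params$norm_window
  total <- sum(track[max(1L, p1 - wn):min(L, p1 + wn)])
  if (total <= 0) return(NULL)
  rel <- -params$display_window:params$display_window
  idx <- p1 + rel
  val <- ifelse(idx >= 1L & idx <= L, track[pmax(pmin(idx, L), 1L)] / total,
                NA_real_)
  names(val) <- rel
  val
}

.site_matrix <- function(tracks, sites, params) {
  profs <- vector("list", nrow(sites))
  kept <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    tr <- tracks[[sites$transcript_id[i]]]
    if (is.null(tr)) next
    p <- normalize_site_window(tr, sites$position[i], params)
    if (is.null(p)) {
      message("site ", sites$transcript_id[i], ":", sites$position[i],
              " dropped: no signal in the normalization window")
      next
    }
    profs[[i]] <- p
    kept[i] <- TRUE
  }
  if (!any(kept)) stop("all sites dropped", call. = FALSE)
  list(mat = do.call(rbind, profs[kept]), sites = sites[kept, ,
                                                        drop = FALSE])
}

#' Metagene profile around editing sites
#'
#' Per relative position, the weighted mean of the window-normalized
#' coverage over all contributing sites. With
#' `weighting = "editing_rate"` the weights are the sites' editing rates
#' and the mean is normalized by the sum of weights over unmasked
#' contributions, so a rate-0 site does not influence the profile; with
#' `"unweighted"` every site counts equally (the mode for unedited control
#' sites). Masked positions (outside the transcript) are excluded from
#' numerator and denominator position by position.
#'
#' @param tracks Named list of per-transcript coverage vectors.
#' @param sites Annotated sites table (needs `transcript_id`, `position`,
#'   and `editing_rate` for weighted mode).
#' @param params A [metagene_params()] object.
#' @return An object of class `metagene_profile`: data.frame with columns
#'   `rel_pos`, `value`, `n_sites`; attributes `weighting`, `norm_window`,
#'   `n_total` (sites contributing), `site_matrix` and `weights` (per-site
#'   normalized windows, for downstream uncertainty estimates).
#' @export
metagene <- function(tracks, sites, params = metagene_params()) {
  if (nrow(sites) == 0L) stop("no sites supplied", call. = FALSE)
  sm <- .site_matrix(tracks, sites, params)
  w <- if (params$weighting == "editing_rate") {
    stopifnot("editing_rate" %in% names(sm$sites))
    sm$sites$editing_rate
  } else rep(1, nrow(sm$sites))
  if (all(w == 0)) stop("all site weights are zero", call. = FALSE)
  mat <- sm$mat
  unmasked <- !is.na(mat)
  wm <- matrix(w, nrow = nrow(mat), ncol = ncol(mat)) * unmasked
  num <- colSums(mat * wm, na.rm = TRUE)
  den <- colSums(wm)
  out <- data.frame(rel_pos = as.integer(colnames(mat)),
                    value = ifelse(den > 0, num / den, NA_real_),
                    n_sites = colSums(unmasked))
  rownames(out) <- NULL
  structure(out,
            class = c("metagene_profile", "data.frame"),
            weighting = params$weighting,
            norm_window = params$norm_window,
            n_total = nrow(mat),
            site_matrix = mat,
            weights = w)
}

#' @export
print.metagene_profile <- function(x, ...) {
  v0 <- x$value[x$rel_pos == 0L]
  cat("Metagene profile: ", attr(x, "n_total"), " sites, positions ",
      min(x$rel_pos), "..", max(x$rel_pos), " (", attr(x, "weighting"),
      "; +/-", attr(x, "norm_window"), " nt normalization)\n", sep = "")
  cat("  value at site (rel_pos 0): ", signif(v0, 4),
      "; window mean: ", signif(mean(x$value, na.rm = TRUE), 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...,
                                  xlab = "position relative to editing site (nt)",
                                  ylab = "mean weighted normalized coverage",
                                  type = "l") {
  graphics::plot(x$rel_pos, x$value, type = type, xlab = xlab, ylab = ylab,
                 ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Codon-position-split metagene profiles
#'
#' Groups sites by the codon position of the edited nucleotide and
#' computes one metagene per group with the parameter overrides of the
#' position-split analysis: no neighbor filtering is applied here (the
#' caller passes all sites) and the normalization window defaults to
#' +/- 1000 nt.
#'
#' @param tracks Named list of coverage vectors.
#' @param sites Annotated sites with a `codon_position` column.
#' @param params A [metagene_params()] object (default `norm_window`
#'   1000).
#' @return Named list `pos1`, `pos2`, `pos3` of `metagene_profile`
#'   objects; empty position groups are omitted with a warning.
#' @export
position_split_metagene <- function(tracks, sites,
                                    params = metagene_params(
                                      norm_window = 1000L)) {
  stopifnot("codon_position" %in% names(sites))
  out <- list()
  for (pos in 1:3) {
    sub <- sites[!is.na(sites$codon_position) &
                   sites$codon_position == pos, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no sites at codon position ", pos, "; group omitted",
              call. = FALSE)
      next
    }
    out[[paste0("pos", pos)]] <- metagene(tracks, sub, params)
  }
  out
}

#' Edited-versus-unedited metagene analysis
#'
#' The full pipeline on annotated sites: neighbor filtering, then an
#' editing-rate-weighted metagene over edited sites and an unweighted
#' metagene over unedited sites (the control that should show no dip).
#'
#' @param tracks Named list of coverage vectors.
#' @param sites Annotated sites table (see [annotate_sites()]).
#' @param params A [metagene_params()] object.
#' @return List with elements `edited` and `unedited`
#'   (`metagene_profile`), either `NULL` when its class has no sites.
#' @export
metagene_analysis <- function(tracks, sites, params = metagene_params()) {
  sites <- filter_neighbor_sites(sites, params$neighbor_radius)
  ed <- sites[sites$status == "edited", , drop = FALSE]
  un <- sites[sites$status == "unedited", , drop = FALSE]
  p_un <- params
  p_un$weighting <- "unweighted"
  list(edited = if (nrow(ed)) metagene(tracks, ed, params) else NULL,
       unedited = if (nrow(un)) metagene(tracks, un, p_un) else NULL)
}
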