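# Transcriptome-wide mapping of bound motifs onto a hairpin structure
# database, annotation of sites as functional (within a Drosha/Dicer
# processing window) or silent, and targetability summaries.

#' Build a motif index over a structure database
#'
#' Extracts every non-canonically paired motif (internal loops and bulges)
#' from each hairpin and keys it by canonical motif identity, so a motif and
#' its strand-swapped writing collide to one key.
#'
#' @param db Named list of [hairpin_structure()] objects.
#' @return Data frame: `key`, `transcript_id`, `motif_class`, spans (1-based
#'   inclusive, including closing pairs). Structures that fail to parse are
#'   reported in the `failed` attribute (named character of messages) and
#'   the rest indexed.
#' @export
build_motif_index <- function(db) {
  failed <- character(0)
  rows <- lapply(db, function(s) {
    mot <- tryCatch(extract_motifs(s), error = function(e) {
      failed[[s$id]] <<- conditionMessage(e)
      NULL
    })
    if (is.null(mot)) return(NULL)
    mot <- mot[!mot$motif_class %in% c("hairpin loop", "fully paired"), ,
               drop = FALSE]
    if (!nrow(mot)) return(NULL)
    data.frame(key = mot$notation, transcript_id = mot$transcript_id,
               motif_class = mot$motif_class,
               top_start = mot$top_start, top_end = mot$top_end,
               bottom_start = mot$bottom_start, bottom_end = mot$bottom_end,
               stringsAsFactors = FALSE)
  })
  idx <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(idx))
    idx <- data.frame(key = character(0), transcript_id = character(0),
                      motif_class = character(0), top_start = integer(0),
                      top_end = integer(0), bottom_start = integer(0),
                      bottom_end = integer(0), stringsAsFactors = FALSE)
  rownames(idx) <- NULL
  attr(idx, "failed") <- failed
  idx
}

#' Map bound motifs onto the transcriptome index
#'
#' One target site per (compound, indexed location) hit; motifs absent from
#' the index simply yield no hits.
#'
#' @param bound Data frame with `compound_id` and `motif` (notation strings,
#'   canonicalized internally).
#' @param index From [build_motif_index()].
#' @return Data frame of target sites (`site_id` identifies the location,
#'   so compound multiplicity at one location is visible); attributes
#'   `n_motifs` (distinct bound motifs with at least one hit), `n_sites`
#'   (distinct locations) and `n_transcripts`.
#' @export
map_binders <- function(bound, index) {
  stopifnot(all(c("compound_id", "motif") %in% names(bound)))
  keys <- unname(vapply(bound$motif, function(m) motif_key(m), character(1)))
  hits <- lapply(seq_len(nrow(bound)), function(i) {
    rows <- index[index$key == keys[i], , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    rownames(rows) <- NULL
    data.frame(compound_id = bound$compound_id[i], motif = keys[i],
               rows, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(sites))
    sites <- data.frame(compound_id = character(0), motif = character(0),
                        key = character(0), transcript_id = character(0),
                        motif_class = character(0), top_start = integer(0),
                        top_end = integer(0), bottom_start = integer(0),
                        bottom_end = integer(0), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  sites$site_id <- if (nrow(sites))
    paste0(sites$transcript_id, ":", sites$top_start, "-", sites$top_end)
  else character(0)
  attr(sites, "n_motifs") <- length(unique(sites$motif))
  attr(sites, "n_sites") <- length(unique(sites$site_id))
  attr(sites, "n_transcripts") <- length(unique(sites$transcript_id))
  sites
}

#' Annotate target sites as functional or silent
#'
#' A site is functional when its motif span (top and bottom strand spans
#' taken together) lies within `window` nucleotides of an annotated Drosha
#' or Dicer scissile position (distance 0 when the position falls inside the
#' span). Sites on transcripts without annotations are silent and flagged
#' `unannotated`.
#'
#' @param sites From [map_binders()].
#' @param db The structure database (for the annotations).
#' @param window Half-width of the functional window in nucleotides
#'   (default 2, i.e. within +/- 2 nt of a scissile position).
#' @return `sites` with `functional`, `nearest_processing_distance` and
#'   `unannotated` columns.
#' @export
annotate_functional <- function(sites, db, window = 2L) {
  n <- nrow(sites)
  fun <- logical(n); dist <- rep(NA_real_, n); unann <- logical(n)
  for (i in seq_len(n)) {
    s <- db[[sites$transcript_id[i]]]
    ann <- s$annotations
    if (is.null(ann) || !nrow(ann)) { unann[i] <- TRUE; next }
    span <- c(seq(sites$top_start[i], sites$top_end[i]),
              if (!is.na(sites$bottom_start[i]))
                seq(sites$bottom_start[i], sites$bottom_end[i]))
    d <- vapply(ann$position, function(p) min(abs(p - span)), numeric(1))
    dist[i] <- min(d)
    fun[i] <- dist[i] <= window
  }
  sites$functional <- fun
  sites$nearest_processing_distance <- dist
  sites$unannotated <- unann
  sites
}

#' Summarize targetability of mapped sites
#'
#' Counts and percentages over unique site locations (compound multiplicity
#' at a location is deduplicated) with transcript-level counts alongside, so
#' either denominator convention is checkable. Percentages are half-up
#' rounded to 1 decimal.
#'
#' @param sites Annotated sites (from [annotate_functional()]), optionally
#'   carrying triage columns (`rnasel_eligible`) from [triage_candidates()].
#' @return List (class `triage_summary`) of counts, percentages and the
#'   denominators used.
#' @export
summarize_targetability <- function(sites) {
  if (!nrow(sites)) {
    return(structure(list(n_sites = 0L, n_transcripts = 0L, n_functional = 0L,
                          n_silent = 0L, n_silent_with_rnasel = 0L,
                          pct_functional = 0, pct_silent = 0,
                          pct_rnasel_eligible = 0,
                          n_transcripts_with_rnasel = 0L,
                          pct_transcripts_rnasel = 0,
                          denominators = list(sites = 0L, transcripts = 0L)),
                     class = "triage_summary"))
  }
  u <- sites[!duplicated(sites$site_id), , drop = FALSE]
  ns <- nrow(u)
  nt <- length(unique(u$transcript_id))
  nf <- sum(u$functional)
  nsil <- ns - nf
  elig <- if ("rnasel_eligible" %in% names(u)) u$rnasel_eligible else
    rep(FALSE, ns)
  elig[is.na(elig)] <- FALSE
  nelig <- sum(elig)
  telig <- length(unique(u$transcript_id[elig]))
  structure(list(
    n_sites = ns, n_transcripts = nt, n_functional = nf, n_silent = nsil,
    n_silent_with_rnasel = nelig,
    pct_functional = round_half_up(100 * nf / ns, 1L),
    pct_silent = round_half_up(100 * nsil / ns, 1L),
    pct_rnasel_eligible = round_half_up(100 * nelig / ns, 1L),
    n_transcripts_with_rnasel = telig,
    pct_transcripts_rnasel = round_half_up(100 * telig / nt, 1L),
    denominators = list(sites = ns, transcripts = nt)),
    class = "triage_summary")
}

#' @export
print.triage_summary <- function(x, ...) {
  cat("Targetability summary\n",
      "  sites: ", x$n_sites, " in ", x$n_transcripts, " transcripts\n",
      "  functional (Drosha/Dicer window): ", x$n_functional, " (",
      x$pct_functional, "% of sites)\n",
      "  silent: ", x$n_silent, " (", x$pct_silent, "%)\n",
      "  RNase-L-eligible (silent, cleavage site within distance rule): ",
      x$n_silent_with_rnasel, " (", x$pct_rnasel_eligible, "% of sites; ",
      x$n_transcripts_with_rnasel, " transcripts)\n", sep = "")
  invisible(x)
}
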