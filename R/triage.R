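# RNase L substrate scanning and RIBOTAC candidate triage. RNase L
# preferentially cleaves at UNN trinucleotides whose leading U is unpaired;
# a biologically silent binding site becomes a degrader candidate when such
# a cleavage site sits within a small number of intervening base pairs along
# the hairpin stem (10 bp by default).

#' Scan a hairpin for RNase L substrate sites (UNN, unpaired U)
#'
#' Reports every position `i` with `sequence[i] == "U"`, the position
#' unpaired, and `i + 2` within bounds. In `strict` mode any additional U
#' inside the trinucleotide must also be unpaired.
#'
#' @param structure A [hairpin_structure()].
#' @param strict Require all Us in the UNN window to be unpaired.
#' @return Data frame: `transcript_id`, `start` (1-based), `trinucleotide`,
#'   `unpaired` (e.g. `"UNN"` mask showing which positions are unpaired),
#'   `loop_context` (motif class of the loop containing the leading U, or
#'   `"exterior"`).
#' @export
scan_rnasel <- function(structure, strict = FALSE) {
  stopifnot(inherits(structure, "hairpin_structure"))
  sc <- .chars(structure$seq)
  unp <- is.na(structure$pt)
  n <- length(sc)
  hits <- integer(0)
  for (i in seq_len(max(0L, n - 2L))) {
    if (sc[i] != "U" || !unp[i]) next
    if (strict) {
      tri <- i:(i + 2L)
      if (any(sc[tri] == "U" & !unp[tri])) next
    }
    hits <- c(hits, i)
  }
  if (!length(hits))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      trinucleotide = character(0), unpaired = character(0),
                      loop_context = character(0), stringsAsFactors = FALSE))
  mot <- extract_motifs(structure)
  context <- vapply(hits, function(i) {
    inside <- which((mot$top_start <= i & i <= mot$top_end) |
                      (!is.na(mot$bottom_start) &
                         mot$bottom_start <= i & i <= mot$bottom_end))
    if (length(inside)) mot$motif_class[inside[1L]] else "exterior"
  }, character(1))
  data.frame(
    transcript_id = structure$id, start = hits,
    trinucleotide = vapply(hits, function(i)
      paste(sc[i:(i + 2L)], collapse = ""), character(1)),
    unpaired = vapply(hits, function(i)
      paste(ifelse(unp[i:(i + 2L)], "u", "p"), collapse = ""), character(1)),
    loop_context = context, stringsAsFactors = FALSE)
}

#' Stem distance between a binding site and a cleavage site
#'
#' The number of base-paired columns strictly between the binding motif's
#' nearest closing pair and the cleavage site's loop, walking along the
#' stem: with the motif loop at nesting depth `k` and the cleavage position
#' at depth `r`, the distance is `max(0, |r - k| - 1)` base pairs (the
#' motif's own closing pair is not counted). Symmetric in argument order; 0
#' when the cleavage loop is immediately adjacent to the motif's closing
#' pair or inside the motif loop itself.
#'
#' @param structure A [hairpin_structure()] carrying both features.
#' @param motif_span Integer vector of the motif's positions (e.g.
#'   `top_start:top_end` plus the bottom span).
#' @param cleavage_pos 1-based position of the cleavage site's leading U.
#' @return Integer base-pair count.
#' @export
stem_distance <- function(structure, motif_span, cleavage_pos) {
  stopifnot(inherits(structure, "hairpin_structure"))
  interior <- motif_span[is.na(structure$pt[motif_span])]
  anchor <- if (length(interior)) interior else motif_span
  k <- min(vapply(anchor, function(p) .nesting_depth(structure, p),
                  numeric(1)))
  if (!is.na(structure$pt[cleavage_pos]))
    stop("cleavage position ", cleavage_pos, " is base-paired", call. = FALSE)
  r <- .nesting_depth(structure, cleavage_pos)
  as.integer(max(0, abs(r - k) - 1))
}

#' Triage silent target sites against RNase L cleavage sites
#'
#' For each silent site, finds the nearest cleavage site on the same
#' transcript by stem distance (ties broken toward the 5'-most site) and
#' accepts the pairing when the distance is at most `max_distance` base
#' pairs (inclusive). Functional sites pass through flagged
#' "bioactive-by-binding" (their activity does not depend on a RIBOTAC);
#' silent sites on transcripts with no cleavage site are emitted with
#' `accepted = FALSE` and `NA` distance.
#'
#' @param sites Annotated target sites (from [annotate_functional()]).
#' @param db Structure database.
#' @param max_distance Maximum stem distance in base pairs (default 10).
#' @param strict Passed to [scan_rnasel()].
#' @return `sites` with `cleavage_start`, `stem_distance_bp`,
#'   `rnasel_eligible` (accepted) and `triage_flag` columns.
#' @export
triage_candidates <- function(sites, db, max_distance = 10L, strict = FALSE) {
  n <- nrow(sites)
  cleav <- rep(NA_integer_, n); dist <- rep(NA_integer_, n)
  acc <- rep(NA, n); flag <- character(n)
  scans <- list()
  for (i in seq_len(n)) {
    if (isTRUE(sites$functional[i])) {
      flag[i] <- "bioactive-by-binding"
      next
    }
    tid <- sites$transcript_id[i]
    s <- db[[tid]]
    if (is.null(scans[[tid]])) scans[[tid]] <- scan_rnasel(s, strict = strict)
    sc <- scans[[tid]]
    if (!nrow(sc)) { acc[i] <- FALSE; flag[i] <- "no-cleavage-site"; next }
    span <- c(seq(sites$top_start[i], sites$top_end[i]),
              if (!is.na(sites$bottom_start[i]))
                seq(sites$bottom_start[i], sites$bottom_end[i]))
    d <- vapply(sc$start, function(p) stem_distance(s, span, p), integer(1))
    best <- which(d == min(d))
    best <- best[which.min(sc$start[best])]  # 5'-most on ties
    cleav[i] <- sc$start[best]
    dist[i] <- d[best]
    acc[i] <- dist[i] <= max_distance
    flag[i] <- if (acc[i]) "ribotac-candidate" else "cleavage-too-far"
  }
  sites$cleavage_start <- cleav
  sites$stem_distance_bp <- dist
  sites$rnasel_eligible <- acc
  sites$triage_flag <- flag
  sites
}
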