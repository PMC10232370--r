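# The selection library: a hairpin cassette displaying a randomized region
# (by default 3 + 3 nucleotides opposite each other, flanked by fixed closing
# pairs), giving 4^6 = 4,096 unique members which can display internal loops,
# bulges or fully paired stretches depending on how the randomized
# nucleotides cross-pair.

#' Define a library cassette
#'
#' @param rand_top,rand_bottom Number of randomized positions on each strand
#'   (default 3 + 3).
#' @param closing_left,closing_right Fixed closing pairs flanking the
#'   randomized region, each a length-2 vector (top base, bottom base); the
#'   exact cassette scaffold is not printed in the source selection design,
#'   so a documented synthetic default (G.C / C.G closings) is used.
#' @param stem_left,stem_right,apical Scaffold helix arms (base-pair strings
#'   read on the top strand) and apical loop used when a full cassette
#'   sequence is needed (e.g. for a thermodynamic folding backend).
#' @return `library_cassette` object.
#' @export
library_cassette <- function(rand_top = 3L, rand_bottom = 3L,
                             closing_left = c("G", "C"),
                             closing_right = c("C", "G"),
                             stem_left = "GGCAGC", stem_right = "GCAG",
                             apical = "GAAA") {
  if (rand_top < 1L || rand_bottom < 1L)
    stop("cassette needs at least one randomized position per strand",
         call. = FALSE)
  stopifnot(.is_pair(closing_left[1L], closing_left[2L]),
            .is_pair(closing_right[1L], closing_right[2L]))
  structure(list(rand_top = as.integer(rand_top),
                 rand_bottom = as.integer(rand_bottom),
                 closing_left = closing_left, closing_right = closing_right,
                 stem_left = stem_left, stem_right = stem_right,
                 apical = apical),
            class = "library_cassette")
}

#' Enumerate all members of a cassette library
#'
#' Full enumeration of the randomized region: `4^(rand_top + rand_bottom)`
#' unique members in lexicographic order of the randomized sequence.
#'
#' @param cassette A [library_cassette()].
#' @return Data frame with `member_id` (the displayed motif in ASCII 5'/3'
#'   notation), `randomized_top`, `randomized_bottom` (bottom written 3'->5',
#'   aligned with the top) and `randomized_sequence`.
#' @export
enumerate_library <- function(cassette = library_cassette()) {
  stopifnot(inherits(cassette, "library_cassette"))
  n <- cassette$rand_top + cassette$rand_bottom
  nts <- c("A", "C", "G", "U")
  grid <- do.call(expand.grid,
                  c(rep(list(nts), n), list(stringsAsFactors = FALSE)))
  # expand.grid varies the first factor fastest; reorder so the randomized
  # sequence is lexicographic
  seqs <- do.call(paste0, rev(grid))
  seqs <- sort(seqs)
  top <- substr(seqs, 1L, cassette$rand_top)
  bottom <- substr(seqs, cassette$rand_top + 1L, n)
  member_id <- paste0("5'", cassette$closing_left[1L], top,
                      cassette$closing_right[1L],
                      "/3'", cassette$closing_left[2L], bottom,
                      cassette$closing_right[2L])
  data.frame(member_id = member_id, randomized_top = top,
             randomized_bottom = bottom, randomized_sequence = seqs,
             stringsAsFactors = FALSE)
}

# Rule-based nested "ladder" classifier for a randomized region flanked by
# fixed closing pairs: pair aligned columns outermost-in while they form
# WC/GU pairs; on a symmetric leftover, a single-register shift that pairs
# the full overlap is called a bulge-containing member; on an asymmetric
# leftover, a contiguous skip on the longer strand that lets the rest pair
# is a bulge of that size. No thermodynamics.
.classify_rand <- function(top, bottom) {
  t <- .chars(top); b <- .chars(bottom)
  a <- length(t); bb <- length(b)
  l <- 0L
  while (l < min(a, bb) && .is_pair(t[l + 1L], b[l + 1L])) l <- l + 1L
  r <- 0L
  while (l + r < min(a, bb) && .is_pair(t[a - r], b[bb - r])) r <- r + 1L
  at <- a - l - r; bt <- bb - l - r
  if (at == 0L && bt == 0L) return("fully paired")
  if (bt == 0L) return(paste0(at, "-nt bulge"))
  if (at == 0L) return(paste0(bt, "-nt bulge"))
  tl <- t[(l + 1L):(a - r)]; bl <- b[(l + 1L):(bb - r)]
  if (at == bt) {
    if (at >= 2L) {
      m <- at
      up <- all(vapply(seq_len(m - 1L),
                       function(i) .is_pair(tl[i], bl[i + 1L]), logical(1)))
      dn <- all(vapply(seq_len(m - 1L),
                       function(i) .is_pair(tl[i + 1L], bl[i]), logical(1)))
      if (up || dn) return("bulge loop")
    }
    return(paste0(at, .TIMES, at, " internal loop"))
  }
  d <- abs(at - bt)
  long <- if (at > bt) tl else bl
  short <- if (at > bt) bl else tl
  m <- length(short)
  for (skip in 0:m) {
    keep <- long[setdiff(seq_along(long), skip + seq_len(d))]
    if (length(keep) == m &&
        all(vapply(seq_len(m), function(i) .is_pair(
          if (at > bt) keep[i] else short[i],
          if (at > bt) short[i] else keep[i]), logical(1))))
      return(paste0(d, "-nt bulge"))
  }
  paste0(min(at, bt), .TIMES, max(at, bt), " internal loop")
}

#' Classify the displayed motif of every library member
#'
#' @param members Data frame from [enumerate_library()].
#' @param cassette The cassette the members came from.
#' @param backend `"ladder"` for the default deterministic rule-based
#'   classifier, or a folding function `function(sequence) -> dot-bracket`
#'   (a thermodynamic backend); with a folding backend the full cassette
#'   sequence is folded and the motif spanning the randomized region is
#'   classified from the predicted structure.
#' @return `members` with a `motif_class` column.
#' @export
classify_members <- function(members, cassette = library_cassette(),
                             backend = "ladder") {
  stopifnot(is.data.frame(members),
            all(c("randomized_top", "randomized_bottom") %in% names(members)))
  if (identical(backend, "ladder")) {
    cls <- vapply(seq_len(nrow(members)), function(i)
      .classify_rand(members$randomized_top[i], members$randomized_bottom[i]),
      character(1))
  } else if (is.function(backend)) {
    cls <- vapply(seq_len(nrow(members)), function(i) {
      sq <- cassette_sequence(cassette, members$randomized_top[i],
                              members$randomized_bottom[i])
      db <- tryCatch(backend(sq), error = function(e)
        stop("folding backend failed on member ", members$member_id[i], ": ",
             conditionMessage(e), call. = FALSE))
      .class_from_fold(cassette, sq, db)
    }, character(1))
  } else stop("unknown backend", call. = FALSE)
  members$motif_class <- cls
  members
}

#' Full cassette sequence for one member
#'
#' Scaffold helix, closing pairs, randomized region and apical loop
#' assembled into a single hairpin sequence (used by folding backends).
#' @param cassette A [library_cassette()].
#' @param top,bottom Randomized nucleotides (bottom written 3'->5').
#' @return Sequence string.
#' @export
cassette_sequence <- function(cassette, top, bottom) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rc <- function(s) paste(rev(comp[.chars(s)]), collapse = "")
  paste0(cassette$stem_left, cassette$closing_left[1L], top,
         cassette$closing_right[1L], cassette$stem_right, cassette$apical,
         rc(cassette$stem_right), cassette$closing_right[2L],
         paste(rev(.chars(bottom)), collapse = ""),
         cassette$closing_left[2L], rc(cassette$stem_left))
}

.class_from_fold <- function(cassette, sq, db) {
  hs <- hairpin_structure("member", sq, db)
  mot <- extract_motifs(hs)
  # randomized region position on the top strand
  r1 <- nchar(cassette$stem_left) + 2L
  r2 <- r1 + cassette$rand_top - 1L
  hit <- which(mot$top_start <= r2 & mot$top_end >= r1 &
                 mot$motif_class != "hairpin loop")
  if (!length(hit)) return("fully paired")
  if (length(hit) > 1L) return("bulge loop")
  mot$motif_class[hit]
}

#' Motif-class distribution report
#'
#' @param classified Data frame with a `motif_class` column (from
#'   [classify_members()]).
#' @return Data frame `(motif_class, count, percent)`, percent half-up
#'   rounded to 1 decimal; counts sum to the library size.
#' @export
library_class_report <- function(classified) {
  if (!nrow(classified)) stop("empty distribution", call. = FALSE)
  tab <- table(classified$motif_class)
  data.frame(motif_class = names(tab), count = as.integer(tab),
             percent = round_half_up(100 * as.integer(tab) / nrow(classified),
                                     1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Number of candidate binding interactions probed
#'
#' Library members crossed with a compound collection.
#' @param n_members Library size (e.g. 4,096).
#' @param n_compounds Compound collection size (e.g. 15,000).
#' @return `n_members * n_compounds`.
#' @export
candidate_interactions <- function(n_members, n_compounds) {
  as.numeric(n_members) * as.numeric(n_compounds)
}
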