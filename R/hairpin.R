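# Hairpin structures: a sequence plus Vienna dot-bracket secondary structure
# (a single stem-loop, no pseudoknots or multibranch junctions), optionally
# carrying Drosha/Dicer processing-site annotations. Coordinates are 0-based
# half-open internally and 1-based inclusive in everything user-facing.

#' Construct a hairpin structure
#'
#' @param id Transcript identifier.
#' @param sequence RNA sequence (A/C/G/U).
#' @param dotbracket Vienna dot-bracket string of the same length; only
#'   `(`, `)` and `.` are allowed (pseudoknot bracket layers are rejected).
#' @param annotations Optional data frame of processing sites with columns
#'   `site_type` (`"Drosha"` or `"Dicer"`) and `position` (1-based scissile
#'   position).
#' @return An object of class `hairpin_structure` with the pairing table
#'   (`pt`, partner index per position, `NA` if unpaired) and the ordered
#'   base-pair list (`pairs`, outermost first).
#' @export
hairpin_structure <- function(id, sequence, dotbracket, annotations = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("T", "U", sequence))
  n <- nchar(sequence)
  if (nchar(dotbracket) != n)
    stop("sequence and structure lengths differ for '", id, "' (", n, " vs ",
         nchar(dotbracket), ")", call. = FALSE)
  sc <- .chars(sequence)
  if (any(!sc %in% c("A", "C", "G", "U")))
    stop("invalid nucleotide in '", id, "'", call. = FALSE)
  dc <- .chars(dotbracket)
  if (any(!dc %in% c("(", ")", ".")))
    stop("unsupported bracket character in '", id,
         "' (pseudoknots are not supported)", call. = FALSE)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (dc[i] == "(") stack <- c(stack, i)
    else if (dc[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets in '", id, "'", call. = FALSE)
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced brackets in '", id, "'", call. = FALSE)
  op <- which(dc == "(")
  pairs <- if (length(op)) cbind(i = op, j = pt[op]) else
    matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j")))
  if (nrow(pairs) > 1L && any(diff(pairs[, "j"]) > 0))
    stop("'", id, "' is not a single hairpin (multibranch junction)",
         call. = FALSE)
  if (!is.null(annotations)) {
    stopifnot(all(c("site_type", "position") %in% names(annotations)))
    if (nrow(annotations) &&
        (any(annotations$position < 1L) || any(annotations$position > n)))
      stop("processing annotation out of bounds for '", id, "'", call. = FALSE)
    if (nrow(annotations) &&
        any(!annotations$site_type %in% c("Drosha", "Dicer")))
      stop("unknown processing site type for '", id, "'", call. = FALSE)
  }
  structure(list(id = id, seq = sequence, db = dotbracket, pt = pt,
                 pairs = pairs, annotations = annotations),
            class = "hairpin_structure")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(">", x$id, " (", nchar(x$seq), " nt, ", nrow(x$pairs), " bp)\n",
      x$seq, "\n", x$db, "\n", sep = "")
  invisible(x)
}

#' Extract structural motifs from a hairpin
#'
#' Walks the stem from the outermost base pair inward. Every non-stacked gap
#' between consecutive pairs becomes an internal loop or bulge motif carrying
#' the nearest closing pair on each side; the apical loop is reported once as
#' a hairpin loop. Every nucleotide inside the outermost pair belongs to
#' exactly one motif interior or one helix; unpaired nucleotides outside the
#' outermost pair are reported in the `external_positions` attribute.
#'
#' @param structure A [hairpin_structure()].
#' @return Data frame with one row per motif: `transcript_id`, `notation`
#'   (canonical motif key), `motif_class`, `top_start`/`top_end` and
#'   `bottom_start`/`bottom_end` (1-based inclusive spans including the
#'   closing pairs; `NA` bottom for the hairpin loop, whose span covers the
#'   loop nucleotides), `top_seq`/`bottom_seq` as read on the transcript.
#'   Attributes: `paired_positions` (all base-paired positions) and
#'   `external_positions`.
#' @export
extract_motifs <- function(structure) {
  stopifnot(inherits(structure, "hairpin_structure"))
  sc <- .chars(structure$seq)
  P <- structure$pairs
  out <- list()
  if (nrow(P) == 0L) {
    res <- .motif_df_empty(structure$id)
    attr(res, "paired_positions") <- integer(0)
    attr(res, "external_positions") <- seq_along(sc)
    return(res)
  }
  for (k in seq_len(nrow(P) - 1L)) {
    i1 <- P[k, "i"]; j1 <- P[k, "j"]
    i2 <- P[k + 1L, "i"]; j2 <- P[k + 1L, "j"]
    if (i2 == i1 + 1L && j2 == j1 - 1L) next  # stacked helix step
    top <- paste(sc[i1:i2], collapse = "")
    bottom <- paste(sc[j1:j2], collapse = "")  # j1 > j2: read 3'->5'
    w <- max(nchar(top), nchar(bottom))
    pad <- function(s) {
      x <- .chars(s); n <- length(x)
      mid <- if (n > 2L) x[2:(n - 1L)] else character(0)
      paste(c(x[1L], mid, rep("_", w - n), x[n]), collapse = "")
    }
    m <- structural_motif(pad(top), pad(bottom))
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = structure$id, notation = format_motif(m),
      motif_class = m$motif_class,
      top_start = i1, top_end = i2, bottom_start = j2, bottom_end = j1,
      top_seq = top, bottom_seq = bottom, stringsAsFactors = FALSE)
  }
  ik <- P[nrow(P), "i"]; jk <- P[nrow(P), "j"]
  hp <- hairpin_loop_motif(paste(sc[(ik + 1L):(jk - 1L)], collapse = ""),
                           c(sc[ik], sc[jk]))
  out[[length(out) + 1L]] <- data.frame(
    transcript_id = structure$id, notation = motif_key(hp),
    motif_class = "hairpin loop",
    top_start = ik + 1L, top_end = jk - 1L,
    bottom_start = NA_integer_, bottom_end = NA_integer_,
    top_seq = hp$loop, bottom_seq = NA_character_, stringsAsFactors = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "paired_positions") <- sort(c(P[, "i"], P[, "j"]))
  ext <- setdiff(seq_along(sc), seq(P[1L, "i"], P[1L, "j"]))
  attr(res, "external_positions") <- ext
  res
}

.motif_df_empty <- function(id) {
  data.frame(transcript_id = character(0), notation = character(0),
             motif_class = character(0), top_start = integer(0),
             top_end = integer(0), bottom_start = integer(0),
             bottom_end = integer(0), top_seq = character(0),
             bottom_seq = character(0), stringsAsFactors = FALSE)
}

# ---- structure database I/O ------------------------------------------------

#' Read a structure database from a dot-bracket file
#'
#' The file holds Vienna-style records: a `>id` header line, the sequence
#' line and the dot-bracket line. Processing-site annotations come from an
#' optional BED-like TSV with columns `transcript_id`, `site_type`,
#' `position` (1-based).
#'
#' @param dbn_file Path to the dot-bracket file.
#' @param annotation_file Optional path to the annotation TSV.
#' @return Named list of [hairpin_structure()] objects.
#' @export
read_structure_db <- function(dbn_file, annotation_file = NULL) {
  lines <- readLines(dbn_file)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no records in ", dbn_file, call. = FALSE)
  ann <- NULL
  if (!is.null(annotation_file)) {
    ann <- utils::read.delim(annotation_file, stringsAsFactors = FALSE)
    stopifnot(all(c("transcript_id", "site_type", "position") %in% names(ann)))
  }
  db <- list()
  for (h in hdr) {
    id <- sub("^>\\s*", "", lines[h])
    if (h + 2L > length(lines))
      stop("truncated record '", id, "' in ", dbn_file, call. = FALSE)
    a <- if (!is.null(ann)) ann[ann$transcript_id == id,
                                c("site_type", "position"), drop = FALSE]
    db[[id]] <- hairpin_structure(id, lines[h + 1L], lines[h + 2L],
                                  annotations = a)
  }
  db
}

#' Write a structure database
#'
#' @param db Named list of [hairpin_structure()] objects.
#' @param dbn_file Output dot-bracket path.
#' @param annotation_file Optional output TSV path for processing
#'   annotations.
#' @return Invisibly, `dbn_file`.
#' @export
write_structure_db <- function(db, dbn_file, annotation_file = NULL) {
  con <- file(dbn_file, "w")
  on.exit(close(con))
  for (s in db) writeLines(c(paste0(">", s$id), s$seq, s$db), con)
  if (!is.null(annotation_file)) {
    rows <- lapply(db, function(s) {
      if (is.null(s$annotations) || !nrow(s$annotations)) return(NULL)
      data.frame(transcript_id = s$id, s$annotations,
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(ann))
      ann <- data.frame(transcript_id = character(0),
                        site_type = character(0), position = integer(0))
    utils::write.table(ann, annotation_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(dbn_file)
}

# Nesting depth of an unpaired position: number of base pairs (i,j) with
# i < p < j. Loops along a single stem are totally ordered by depth, which is
# what the stem-distance rule counts over.
.nesting_depth <- function(structure, p) {
  P <- structure$pairs
  if (!nrow(P)) return(0L)
  sum(P[, "i"] < p & p < P[, "j"])
}
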