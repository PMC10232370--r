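# Two-strand RNA structural motifs (internal loops, bulges, fully paired
# stretches) in the field's 5'.../3'... loop notation: the top strand is
# written 5'->3', the bottom strand 3'->5', so aligned columns are pairing
# partners and "_" marks a gap (a strand contributing no nucleotide to a
# column). The two terminal columns are the closing base pairs; everything
# between them is loop.

.PRIME5 <- "5′"
.PRIME3 <- "3′"
.TIMES <- "×"

.VALID_PAIRS <- c("GC", "CG", "AU", "UA", "GU", "UG")

.is_pair <- function(x, y) paste0(x, y) %in% .VALID_PAIRS

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Construct a structural motif from aligned strands
#'
#' @param top Top strand, written 5' to 3', using characters `A`, `C`, `G`,
#'   `U` and `_` (gap).
#' @param bottom Bottom strand, written 3' to 5' so that it aligns
#'   column-by-column with `top`; same alphabet.
#'
#' @return An object of class `structural_motif` with fields `top`, `bottom`
#'   (canonical layout: interior nucleotides left-aligned, gaps at the right
#'   end of the interior; the reading with fewer gaps on the top strand),
#'   `loop_top`, `loop_bottom` (interior nucleotides per strand),
#'   `closing_pairs` (2-row matrix) and `motif_class`.
#'
#' GU wobble counts as paired throughout (closing pairs and helices).
#' @export
structural_motif <- function(top, bottom) {
  stopifnot(is.character(top), length(top) == 1L,
            is.character(bottom), length(bottom) == 1L)
  tc <- .chars(top); bc <- .chars(bottom)
  if (length(tc) != length(bc))
    stop("motif strands have unequal aligned lengths (", length(tc), " vs ",
         length(bc), ")", call. = FALSE)
  n <- length(tc)
  if (n < 2L)
    stop("motif must have aligned length >= 2 (two closing columns)",
         call. = FALSE)
  bad <- which(!(tc %in% c("A", "C", "G", "U", "_")) |
                 !(bc %in% c("A", "C", "G", "U", "_")))
  if (length(bad))
    stop("invalid character in motif at column ", bad[1L], call. = FALSE)
  for (j in c(1L, n)) {
    if (tc[j] == "_" || bc[j] == "_")
      stop("gap in terminal column ", j, ": closing columns must be base pairs",
           call. = FALSE)
    if (!.is_pair(tc[j], bc[j]))
      stop("terminal column ", j, " (", tc[j], "/", bc[j],
           ") is not a Watson-Crick or GU pair", call. = FALSE)
  }
  gapgap <- which(tc == "_" & bc == "_")
  if (length(gapgap))
    stop("column ", gapgap[1L], " is gap/gap", call. = FALSE)

  cn <- .canonical_strands(paste(tc, collapse = ""), paste(bc, collapse = ""))
  tc <- .chars(cn[1L]); bc <- .chars(cn[2L]); n <- length(tc)
  interior <- if (n > 2L) seq(2L, n - 1L) else integer(0)
  loop_top <- paste(tc[interior][tc[interior] != "_"], collapse = "")
  loop_bottom <- paste(bc[interior][bc[interior] != "_"], collapse = "")
  m <- structure(list(
    top = cn[1L], bottom = cn[2L],
    loop_top = loop_top, loop_bottom = loop_bottom,
    closing_pairs = matrix(c(tc[1L], bc[1L], tc[n], bc[n]), nrow = 2L,
                           byrow = TRUE,
                           dimnames = list(c("left", "right"),
                                           c("top", "bottom")))
  ), class = "structural_motif")
  m$motif_class <- classify_motif(m)
  m
}

# Canonical layout and orientation. Interior nucleotides are left-aligned
# within the interior (gaps pushed right); between the two strand-swap
# readings of the same physical motif, the one with fewer gaps on the top
# strand wins (this keeps the paper's bulge notation, e.g. 5'GAU/3'C_A,
# canonical), ties broken lexicographically by top then bottom strand.
.canonical_strands <- function(top, bottom) {
  relayout <- function(t, b) {
    tc <- .chars(t); bc <- .chars(b); n <- length(tc)
    ti <- if (n > 2L) tc[2:(n - 1L)] else character(0)
    bi <- if (n > 2L) bc[2:(n - 1L)] else character(0)
    tn <- ti[ti != "_"]; bn <- bi[bi != "_"]
    w <- max(length(tn), length(bn))
    pad <- function(x) c(x, rep("_", w - length(x)))
    c(paste(c(tc[1L], pad(tn), tc[n]), collapse = ""),
      paste(c(bc[1L], pad(bn), bc[n]), collapse = ""))
  }
  rev_str <- function(s) paste(rev(.chars(s)), collapse = "")
  r1 <- relayout(top, bottom)
  r2 <- relayout(rev_str(bottom), rev_str(top))
  g1 <- sum(.chars(r1[1L]) == "_"); g2 <- sum(.chars(r2[1L]) == "_")
  if (g1 < g2) return(r1)
  if (g2 < g1) return(r2)
  k1 <- paste(r1, collapse = "/"); k2 <- paste(r2, collapse = "/")
  if (k1 <= k2) r1 else r2
}

#' Parse a motif from 5'/3' loop notation
#'
#' Accepts strings such as `"5'GAU/3'C_A"` (either the typographic prime
#' `′` or an ASCII apostrophe). The top side is the 5'->3' strand, the
#' bottom side the 3'->5' strand, aligned column-wise; `_` is a gap. The
#' literature often omits gap characters for asymmetric loops (e.g.
#' `"5'UUU/3'GUCA"`); with `pad = TRUE` (default) the shorter interior is
#' padded with gaps, with `pad = FALSE` unequal lengths are an error.
#'
#' @param notation Motif string.
#' @param pad Pad the shorter interior with gap characters when the two
#'   sides have unequal length.
#' @return A [structural_motif()].
#' @examples
#' parse_motif("5'GAU/3'C_A")   # the pre-miR-155 A bulge
#' parse_motif("5'UUCG/3'ACCC") # a 2x2 internal loop
#' @export
parse_motif <- function(notation, pad = TRUE) {
  stopifnot(is.character(notation), length(notation) == 1L)
  s <- gsub("'", "′", notation, fixed = TRUE)
  rx <- "^5′([ACGU_]+)/3′([ACGU_]+)$"
  if (!grepl(rx, s))
    stop("malformed motif notation: ", notation,
         " (expected 5'<ACGU_>/3'<ACGU_>)", call. = FALSE)
  top <- sub(rx, "\\1", s); bottom <- sub(rx, "\\2", s)
  nt <- nchar(top); nb <- nchar(bottom)
  if (nt != nb) {
    if (!pad || min(nt, nb) < 2L)
      stop("motif strands have unequal lengths (", nt, " vs ", nb,
           ") and cannot be aligned", call. = FALSE)
    w <- max(nt, nb)
    pad_interior <- function(s, w) {
      x <- .chars(s); n <- length(x)
      mid <- if (n > 2L) x[2:(n - 1L)] else character(0)
      paste(c(x[1L], mid, rep("_", w - n), x[n]), collapse = "")
    }
    if (nt < w) top <- pad_interior(top, w) else bottom <- pad_interior(bottom, w)
  }
  structural_motif(top, bottom)
}

#' Format a motif in canonical 5'/3' notation
#'
#' @param m A [structural_motif()].
#' @param ascii Use ASCII apostrophes instead of typographic primes.
#' @return Notation string; `format_motif(parse_motif(s))` is the canonical
#'   form of `s` (round trip).
#' @export
format_motif <- function(m, ascii = FALSE) {
  stopifnot(inherits(m, "structural_motif"))
  s <- paste0(.PRIME5, m$top, "/", .PRIME3, m$bottom)
  if (ascii) gsub("′", "'", s) else s
}

#' @export
print.structural_motif <- function(x, ...) {
  cat(format_motif(x), " [", x$motif_class, "]\n", sep = "")
  invisible(x)
}

#' Classify a motif
#'
#' Pure function of the gap/nucleotide layout: with `a` interior nucleotides
#' on one strand and `b` on the other, `a,b >= 1` is an internal loop
#' (labelled `min x max`, e.g. "1x2 internal loop"), `b = 0` an `a`-nt
#' bulge, no interior at all is "fully paired". Hairpin-loop motifs (from
#' [extract_motifs()]) classify as "hairpin loop".
#'
#' @param m A [structural_motif()] or hairpin-loop motif.
#' @return Class label string.
#' @export
classify_motif <- function(m) {
  if (inherits(m, "hairpin_loop_motif")) return("hairpin loop")
  stopifnot(inherits(m, "structural_motif"))
  a <- nchar(m$loop_top); b <- nchar(m$loop_bottom)
  if (a == 0L && b == 0L) return("fully paired")
  if (b == 0L) return(paste0(a, "-nt bulge"))
  if (a == 0L) return(paste0(b, "-nt bulge"))
  lo <- min(a, b); hi <- max(a, b)
  paste0(lo, .TIMES, hi, " internal loop")
}

#' Canonical identity key of a motif
#'
#' Two motifs are the same physical fold iff their keys are equal; the key is
#' the canonical (orientation- and layout-normalized) notation.
#' @param m A motif or notation string.
#' @return Character key.
#' @export
motif_key <- function(m) {
  if (is.character(m)) m <- parse_motif(m)
  if (inherits(m, "hairpin_loop_motif"))
    return(paste0("HP:", m$closing[1L], "|", m$loop, "|", m$closing[2L]))
  format_motif(m)
}

#' Test whether two motifs are equivalent
#'
#' True iff one motif equals the other after swapping the top and bottom
#' strands (with 5'/3' re-orientation). Equivalence is reflexive, symmetric
#' and transitive because both motifs reduce to a canonical key.
#'
#' @param m1,m2 Motifs or notation strings.
#' @return Logical.
#' @export
motifs_equivalent <- function(m1, m2) {
  identical(motif_key(m1), motif_key(m2))
}

#' Hairpin (apical) loop motif
#'
#' The single-stranded loop closed by one base pair at the top of a hairpin.
#' @param loop Loop nucleotides, 5' to 3'.
#' @param closing Length-2 character vector, the closing pair (5' base,
#'   3' base).
#' @return An object of classes `hairpin_loop_motif`, `structural_motif`.
#' @export
hairpin_loop_motif <- function(loop, closing) {
  stopifnot(length(closing) == 2L, .is_pair(closing[1L], closing[2L]))
  structure(list(loop = loop, closing = closing,
                 motif_class = "hairpin loop"),
            class = c("hairpin_loop_motif", "structural_motif"))
}

#' @export
print.hairpin_loop_motif <- function(x, ...) {
  cat("hairpin loop ", x$closing[1L], "[", x$loop, "]", x$closing[2L], "\n",
      sep = "")
  invisible(x)
}
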