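# Enrichment statistics for library-versus-library selections: each motif
# has a read count in the selected pool and in the starting (input) pool;
# enrichment is quantified by the pooled two-proportion z-statistic (Z_obs)
# and motifs with Z_obs above a fixed threshold (8 by default) are called
# bound. The pooled form is used because the selection literature describes
# the statistic as a pooled population comparison without printing the
# formula; no continuity correction and no pseudocounts by default
# (a +0.5 pseudocount is available via `pseudocount`).

#' Pooled two-proportion enrichment statistic (Z_obs)
#'
#' `z = (phi_sel - phi_in) / sqrt(p(1-p)(1/n_sel + 1/n_in))` with
#' `phi = k/n` and pooled `p = (k_sel + k_in)/(n_sel + n_in)`. Returns 0
#' where the pooled proportion is degenerate (0 or 1). Antisymmetric under
#' swapping the two pools. Vectorized over counts.
#'
#' @param k_sel,k_in Reads of the motif in the selected / input pool.
#' @param n_sel,n_in Total pool depths (> 0).
#' @param pseudocount Added to each `k` (and twice to each `n`) before
#'   computing proportions; default 0.
#' @return Numeric vector of z values.
#' @export
zobs <- function(k_sel, n_sel, k_in, n_in, pseudocount = 0) {
  if (any(n_sel <= 0) || any(n_in <= 0))
    stop("pool depths must be positive", call. = FALSE)
  if (any(k_sel < 0) || any(k_in < 0) || any(k_sel > n_sel) || any(k_in > n_in))
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  k1 <- k_sel + pseudocount; k2 <- k_in + pseudocount
  n1 <- n_sel + 2 * pseudocount; n2 <- n_in + 2 * pseudocount
  p <- (k1 + k2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  z <- ifelse(p <= 0 | p >= 1, 0, (k1 / n1 - k2 / n2) / se)
  as.numeric(z)
}

#' Per-motif enrichment table
#'
#' @param counts Data frame with columns `motif_id`, `k_sel`, `k_in`.
#' @param n_sel,n_in Pool depths; default the column sums (complete table).
#' @param threshold Bound-call threshold on `zobs` (strict `>`, one-sided:
#'   enrichment only).
#' @param pseudocount Passed to [zobs()].
#' @return Data frame `motif_id`, `phi_sel`, `phi_in`, `zobs`, `bound`.
#' @export
zobs_table <- function(counts, n_sel = sum(counts$k_sel),
                       n_in = sum(counts$k_in), threshold = 8,
                       pseudocount = 0) {
  stopifnot(all(c("motif_id", "k_sel", "k_in") %in% names(counts)))
  z <- zobs(counts$k_sel, n_sel, counts$k_in, n_in, pseudocount = pseudocount)
  data.frame(motif_id = counts$motif_id,
             phi_sel = counts$k_sel / n_sel, phi_in = counts$k_in / n_in,
             zobs = z, bound = z > threshold, stringsAsFactors = FALSE)
}

#' Call bound motifs
#'
#' @param results Data frame with `motif_id` and `zobs` (e.g. from
#'   [zobs_table()]).
#' @param threshold Strict lower bound on `zobs` (default 8).
#' @return Character vector of bound motif ids.
#' @export
call_bound <- function(results, threshold = 8) {
  stopifnot(threshold > 0)
  if (!nrow(results)) return(character(0))
  results$motif_id[results$zobs > threshold]
}

#' Position frequency matrix of the top enriched motifs (LOGO matrix)
#'
#' Motifs are ranked by `zobs` (ties broken by lexicographic motif order),
#' the top fraction retained (`ceiling(top_fraction * n)`), and per-column
#' nucleotide frequencies computed over their sequences. Motifs of unequal
#' length are grouped by length and one matrix returned per length.
#'
#' @param results Data frame with `motif_id` (the motif sequence whose
#'   characters are tallied) and `zobs`.
#' @param top_fraction Fraction of motifs to retain, in (0, 1]; default
#'   0.005 (the top 0.5%).
#' @param sequences Optional character vector (parallel to rows) to tally
#'   instead of `motif_id` (e.g. the randomized region only).
#' @return A matrix with rows A/C/G/U (plus `_` if gaps occur) and one
#'   column per position, each column summing to 1 — or a named list of such
#'   matrices when several lengths are present. The retained motif ids are
#'   in the `motifs` attribute.
#' @export
logo_matrix <- function(results, top_fraction = 0.005, sequences = NULL) {
  if (!nrow(results)) stop("empty motif set", call. = FALSE)
  stopifnot(top_fraction > 0, top_fraction <= 1)
  seqs <- if (is.null(sequences)) results$motif_id else sequences
  ord <- order(-results$zobs, seqs)
  keep <- ord[seq_len(ceiling(top_fraction * nrow(results)))]
  seqs <- seqs[keep]
  one <- function(ss) {
    chars <- strsplit(ss, "", fixed = TRUE)
    mat <- do.call(cbind, lapply(seq_len(nchar(ss[1L])), function(j) {
      cj <- vapply(chars, `[`, character(1), j)
      lv <- c("A", "C", "G", "U", if (any(cj == "_")) "_")
      tabulate(factor(cj, levels = lv), nbins = length(lv)) / length(cj)
    }))
    rownames(mat) <- c("A", "C", "G", "U",
                       if (nrow(mat) == 5L) "_")
    colnames(mat) <- seq_len(ncol(mat))
    mat
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1L) {
    out <- one(seqs)
    attr(out, "motifs") <- results$motif_id[keep]
    return(out)
  }
  split_seqs <- split(seqs, lens)
  out <- lapply(split_seqs, one)
  attr(out, "motifs") <- results$motif_id[keep]
  out
}

#' Motif-class enrichment among bound motifs
#'
#' For each motif class, the per-compound bound fractions (the replicates)
#' are compared to the library background fraction with a two-tailed
#' one-sample t-test (`df = n_compounds - 1`). Classes with fewer than two
#' replicate values are flagged and get an `NA` p-value.
#'
#' @param bound_fractions Data frame or matrix: rows = compounds, columns =
#'   motif classes, entries = fraction of that compound's bound motifs in
#'   the class.
#' @param background Named numeric vector of library background fractions
#'   (same class names).
#' @return Data frame per class: `fraction_bound` (mean over compounds),
#'   `fraction_background`, `t`, `p_value`, `direction`, `n_compounds`,
#'   `flagged`.
#' @export
class_enrichment <- function(bound_fractions, background) {
  bf <- as.data.frame(bound_fractions)
  cls <- intersect(names(bf), names(background))
  if (!length(cls)) stop("no shared motif classes", call. = FALSE)
  rows <- lapply(cls, function(cl) {
    x <- bf[[cl]]; mu <- background[[cl]]
    n <- sum(!is.na(x))
    if (n < 2L) {
      return(data.frame(motif_class = cl, fraction_bound = mean(x, na.rm = TRUE),
                        fraction_background = mu, t = NA_real_,
                        p_value = NA_real_, direction = NA_character_,
                        n_compounds = n, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    if (stats::sd(x, na.rm = TRUE) == 0) {
      tt <- list(statistic = if (mean(x) == mu) 0 else Inf * sign(mean(x) - mu),
                 p.value = if (mean(x) == mu) 1 else 0)
    } else {
      ht <- stats::t.test(x, mu = mu)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    data.frame(motif_class = cl, fraction_bound = mean(x, na.rm = TRUE),
               fraction_background = mu, t = tt$statistic,
               p_value = tt$p.value,
               direction = if (mean(x, na.rm = TRUE) >= mu) "enriched"
                           else "depleted",
               n_compounds = n, flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a selection count table
#'
#' TSV with columns `motif_id`, `k_sel`, `k_in`.
#' @param path File path.
#' @return Data frame.
#' @export
read_selection_counts <- function(path) {
  x <- read_tsv(path)
  stopifnot(all(c("motif_id", "k_sel", "k_in") %in% names(x)))
  x
}
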