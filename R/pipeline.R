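# End-to-end triage pipeline and report arithmetic. The pipeline runs the
# stages in order — enrichment (Z_obs), bound-motif calling, transcriptome
# mapping, functional-site annotation, RNase L triage, summary — and emits a
# report carrying every count, percentage and per-candidate row plus the
# resolved configuration, so a rerun with the same inputs and seed is
# reproducible.

#' Pipeline configuration
#'
#' Defaults are the thresholds of the triage procedure: bound call at
#' `Z_obs > 8`, RIBOTAC eligibility within 10 bp along the stem, LOGO
#' analysis over the top 0.5% of enriched motifs, chemical dissimilarity
#' below Tanimoto 0.7, functional window of +/- 2 nt around a scissile
#' position.
#'
#' @param zobs_threshold,max_distance_bp,top_fraction,tanimoto_threshold,functional_window
#'   Stage thresholds.
#' @param pseudocount Passed to [zobs_table()].
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(zobs_threshold = 8, max_distance_bp = 10L,
                            top_fraction = 0.005, tanimoto_threshold = 0.7,
                            functional_window = 2L, pseudocount = 0) {
  structure(list(zobs_threshold = zobs_threshold,
                 max_distance_bp = max_distance_bp,
                 top_fraction = top_fraction,
                 tanimoto_threshold = tanimoto_threshold,
                 functional_window = functional_window,
                 pseudocount = pseudocount),
            class = "pipeline_config")
}

#' Run the triage pipeline
#'
#' @param selections Either a named list of selection count tables (name =
#'   compound id; each a data frame `motif_id`, `k_sel`, `k_in`, with motif
#'   ids in 5'/3' notation) or `NULL` when `bound` is given directly.
#' @param db Structure database (named list of [hairpin_structure()]).
#' @param bound Optional precomputed compound->motif table (`compound_id`,
#'   `motif`), bypassing the enrichment stage.
#' @param config A [pipeline_config()].
#' @return Report list: `config`, per-compound enrichment tables, the bound
#'   table, annotated and triaged sites, and the [summarize_targetability()]
#'   summary.
#' @export
run_pipeline <- function(selections = NULL, db, bound = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  enrichment <- NULL
  if (is.null(bound)) {
    if (is.null(selections) || !length(selections)) {
      bound <- data.frame(compound_id = character(0), motif = character(0),
                          stringsAsFactors = FALSE)
    } else {
      enrichment <- lapply(selections, function(cc)
        zobs_table(cc, threshold = config$zobs_threshold,
                   pseudocount = config$pseudocount))
      bound <- do.call(rbind, lapply(names(enrichment), function(cid) {
        ids <- call_bound(enrichment[[cid]],
                          threshold = config$zobs_threshold)
        if (!length(ids)) return(NULL)
        data.frame(compound_id = cid, motif = ids, stringsAsFactors = FALSE)
      }))
      if (is.null(bound))
        bound <- data.frame(compound_id = character(0),
                            motif = character(0), stringsAsFactors = FALSE)
    }
  }
  index <- build_motif_index(db)
  sites <- map_binders(bound, index)
  sites <- annotate_functional(sites, db, window = config$functional_window)
  sites <- triage_candidates(sites, db,
                             max_distance = config$max_distance_bp)
  summary <- summarize_targetability(sites)
  list(config = unclass(config), enrichment = enrichment, bound = bound,
       n_bound_motifs = length(unique(bound$motif)),
       sites = sites, summary = unclass(summary))
}

#' Write a pipeline report as JSON
#'
#' @param report From [run_pipeline()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

#' Percentage table from labeled count pairs
#'
#' `percent = 100 * numerator / denominator`, rounded half-up to the stated
#' decimals (the convention behind printed selectivity figures such as
#' 29/13,332 -> 0.22%). Rows with a zero denominator are flagged and
#' skipped; the raw ratio is retained.
#'
#' @param numerator,denominator Integer vectors.
#' @param labels Row labels.
#' @param decimals Decimals per row (recycled).
#' @return Data frame `label`, `numerator`, `denominator`, `ratio`,
#'   `percent`; skipped rows (zero denominator) in the `skipped` attribute.
#' @export
ratio_report <- function(numerator, denominator,
                         labels = paste0("ratio", seq_along(numerator)),
                         decimals = 1L) {
  stopifnot(length(numerator) == length(denominator))
  decimals <- rep_len(decimals, length(numerator))
  bad <- denominator == 0
  out <- data.frame(label = labels[!bad], numerator = numerator[!bad],
                    denominator = denominator[!bad],
                    ratio = numerator[!bad] / denominator[!bad],
                    percent = round_half_up(
                      100 * numerator[!bad] / denominator[!bad],
                      decimals[!bad]),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- labels[bad]
  out
}
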