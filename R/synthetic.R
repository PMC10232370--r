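# Synthetic-data generators: every input the triage pipeline consumes can be
# generated with planted ground truth, so each stage is testable without any
# external download. All generators are deterministic under a fixed seed
# (R's Mersenne-Twister; the seed and generator name are recorded in the
# returned ground truth).

.RNG_ID <- "R-MersenneTwister"

#' Simulate a selection experiment (selected vs input pool counts)
#'
#' The input pool is a multinomial draw over uniform motif weights; the
#' selected pool a multinomial draw over the same weights multiplied by the
#' planted fold-enrichments and renormalized. The multinomial pool model
#' reflects fixed sequencing depth per pool.
#'
#' @param n_motifs Number of motifs in the library.
#' @param enriched Named numeric vector: motif id -> fold enrichment
#'   (folds >= 0; ids must be in `motif_ids`).
#' @param depth_sel,depth_in Sequencing depth of each pool.
#' @param seed Integer seed.
#' @param motif_ids Optional explicit ids (default `M0001`...).
#' @return List `counts` (data frame `motif_id`, `k_sel`, `k_in`) and
#'   `truth` (enriched map, depths, seed, generator id).
#' @export
gen_selection <- function(n_motifs, enriched = numeric(0), depth_sel = 1e5,
                          depth_in = 1e5, seed = 1L, motif_ids = NULL) {
  if (n_motifs < 1L || depth_sel <= 0 || depth_in <= 0)
    stop("invalid generator parameters", call. = FALSE)
  if (any(enriched < 0)) stop("fold enrichments must be >= 0", call. = FALSE)
  if (is.null(motif_ids)) motif_ids <- sprintf("M%05d", seq_len(n_motifs))
  stopifnot(length(motif_ids) == n_motifs, !anyDuplicated(motif_ids))
  if (length(enriched) && !all(names(enriched) %in% motif_ids))
    stop("enriched ids not in motif universe", call. = FALSE)
  w_in <- rep(1, n_motifs)
  w_sel <- w_in
  w_sel[match(names(enriched), motif_ids)] <- enriched
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  k_in <- as.integer(stats::rmultinom(1L, depth_in, w_in))
  k_sel <- as.integer(stats::rmultinom(1L, depth_sel, w_sel))
  list(counts = data.frame(motif_id = motif_ids, k_sel = k_sel, k_in = k_in,
                           stringsAsFactors = FALSE),
       truth = list(enriched = as.list(enriched), depth_sel = depth_sel,
                    depth_in = depth_in, n_motifs = n_motifs, seed = seed,
                    generator = .RNG_ID))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- hairpin construction --------------------------------------------------

.STEM_PAIRS <- c("GC", "CG", "AU", "UA")

#' Build a single hairpin with planted features
#'
#' Features are laid out from the root of the stem toward the apical loop.
#' A feature is either a planted binding motif (given in 5'/3' notation) or
#' an RNase L substrate loop (`unn`): a 1x1 internal loop whose top interior
#' nucleotide is an unpaired U, the only unpaired U the construction allows,
#' so the cleavage-site scanner finds exactly the planted sites. All other
#' stem positions are random Watson-Crick pairs and the apical loop is
#' U-free.
#'
#' @param id Transcript id.
#' @param features List of features, each `list(type = "motif"|"unn",
#'   stem_before = <n random stem pairs preceding it>, notation = <motif
#'   notation, for type "motif">)`.
#' @param stem_after Random stem pairs between the last feature and the
#'   apical loop.
#' @param apical Apical loop sequence (default "GCAA").
#' @return List `structure` ([hairpin_structure()], no annotations yet) and
#'   `placed`: per feature the type, notation, 1-based spans, interior
#'   nesting depth and (for `unn`) the leading-U position.
#' @export
build_hairpin <- function(id, features, stem_after = 4L, apical = "GCAA") {
  L <- character(0); R <- character(0)  # R collected outer -> inner
  Ldb <- character(0); Rdb <- character(0)
  depth <- 0L
  placed <- list()
  add_stems <- function(k) {
    for (q in seq_len(k)) {
      pr <- .chars(sample(.STEM_PAIRS, 1L))
      L <<- c(L, pr[1L]); R <<- c(R, pr[2L])
      Ldb <<- c(Ldb, "("); Rdb <<- c(Rdb, ")")
      depth <<- depth + 1L
    }
  }
  for (f in features) {
    add_stems(f$stem_before)
    if (f$type == "motif") {
      m <- parse_motif(f$notation)
      tc <- .chars(m$top); bc <- .chars(m$bottom); n <- length(tc)
      top_start <- length(L) + 1L
      rstart <- length(R) + 1L
      # outer closing
      L <- c(L, tc[1L]); R <- c(R, bc[1L])
      Ldb <- c(Ldb, "("); Rdb <- c(Rdb, ")")
      depth <- depth + 1L
      int_depth <- depth
      for (j in seq(2L, n - 1L)) {
        if (tc[j] != "_") { L <- c(L, tc[j]); Ldb <- c(Ldb, ".") }
        if (bc[j] != "_") { R <- c(R, bc[j]); Rdb <- c(Rdb, ".") }
      }
      L <- c(L, tc[n]); R <- c(R, bc[n])
      Ldb <- c(Ldb, "("); Rdb <- c(Rdb, ")")
      depth <- depth + 1L
      placed[[length(placed) + 1L]] <- list(
        type = "motif", notation = format_motif(m),
        top_start = top_start, top_end = length(L),
        rstart = rstart, rend = length(R), interior_depth = int_depth)
    } else if (f$type == "unn") {
      pr1 <- c("G", "C"); pr2 <- c("C", "G")
      rstart <- length(R) + 1L
      top_start <- length(L) + 1L
      L <- c(L, pr1[1L]); R <- c(R, pr1[2L])
      Ldb <- c(Ldb, "("); Rdb <- c(Rdb, ")")
      depth <- depth + 1L
      int_depth <- depth
      u_pos <- length(L) + 1L
      L <- c(L, "U"); Ldb <- c(Ldb, ".")
      R <- c(R, "A"); Rdb <- c(Rdb, ".")  # bottom interior, unpaired non-U
      L <- c(L, pr2[1L]); R <- c(R, pr2[2L])
      Ldb <- c(Ldb, "("); Rdb <- c(Rdb, ")")
      depth <- depth + 1L
      placed[[length(placed) + 1L]] <- list(
        type = "unn", u_pos = u_pos, top_start = top_start,
        top_end = length(L), rstart = rstart, rend = length(R),
        interior_depth = int_depth)
    } else stop("unknown feature type: ", f$type, call. = FALSE)
  }
  add_stems(stem_after)
  total <- length(L) + nchar(apical) + length(R)
  seqn <- paste0(paste(L, collapse = ""), apical,
                 paste(rev(R), collapse = ""))
  db <- paste0(paste(Ldb, collapse = ""),
               strrep(".", nchar(apical)), paste(rev(Rdb), collapse = ""))
  for (k in seq_along(placed)) {
    p <- placed[[k]]
    placed[[k]]$bottom_start <- total - p$rend + 1L
    placed[[k]]$bottom_end <- total - p$rstart + 1L
    placed[[k]]$rstart <- NULL; placed[[k]]$rend <- NULL
  }
  list(structure = hairpin_structure(id, seqn, db), placed = placed)
}

#' Default triage plan mirroring the study's miRNA-mapping counts
#'
#' 13 distinct binding motifs placed 114 times across 111 hairpins (three
#' hairpins carry two sites), 33 placements inside a Drosha/Dicer processing
#' window, and 55 of the 81 silent placements with an RNase L substrate loop
#' within 10 bp along the stem (planted distances cycle over 3, 5, 7 and
#' 10); 15 silent placements get a cleavage loop at 12 bp (beyond the rule)
#' and 11 get none.
#'
#' @return Plan list understood by [gen_structure_db()].
#' @export
triage_plan_default <- function() {
  list(n_transcripts = 111L, n_placements = 114L, n_functional = 33L,
       n_eligible = 55L, n_far = 15L,
       eligible_distances = c(3L, 5L, 7L, 10L), far_distance = 12L,
       motifs = planted_motif_set())
}

#' The planted binding-motif set
#'
#' Thirteen pairwise-inequivalent motifs (bulges and internal loops with
#' interiors over A/C/G, closings G.C and C.G) used by the default plan.
#' Interiors avoid U so planted cleavage loops stay the only unpaired Us.
#' @return Character vector of notations.
#' @export
planted_motif_set <- function() {
  m <- c("5'GAC/3'C_G", "5'GCC/3'C_G", "5'GGC/3'C_G",
         "5'GAAC/3'C__G", "5'GCCC/3'C__G",
         "5'GAC/3'CAG", "5'GAC/3'CCG", "5'GAC/3'CGG",
         "5'GCC/3'CCG", "5'GGC/3'CGG",
         "5'GAAC/3'CAAG", "5'GAAC/3'CCCG",
         "5'GAAAC/3'CAAAG")
  keys <- vapply(m, motif_key, character(1))
  stopifnot(!anyDuplicated(keys))
  unname(keys)
}

#' Generate a hairpin structure database with planted ground truth
#'
#' Executes a plan (see [triage_plan_default()]): every hairpin is a valid
#' sequence/dot-bracket pair; planted binding motifs, processing windows and
#' UNN cleavage loops appear at recorded coordinates and stem distances;
#' everything else is fully paired stem, so the extractors and scanners find
#' exactly what was planted. Functional placements get a Drosha or Dicer
#' scissile annotation at the motif (distance 0); every transcript also
#' carries a distal Drosha annotation near the stem base, so no transcript
#' is unannotated.
#'
#' @param plan Plan list; default [triage_plan_default()].
#' @param seed Integer seed.
#' @return List `db` (named list of [hairpin_structure()]), `truth`
#'   (placements data frame with functional/eligibility flags and planted
#'   distances, plan, seed, generator id).
#' @export
gen_structure_db <- function(plan = triage_plan_default(), seed = 1L) {
  motifs <- plan$motifs
  nP <- plan$n_placements; nT <- plan$n_transcripts
  nF <- plan$n_functional; nE <- plan$n_eligible; nFar <- plan$n_far
  n_double <- max(0L, nP - nT)  # transcripts carrying two sites
  if (nF < 2L * n_double || nF + nE + nFar > nP)
    stop("infeasible plan", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  # placement table: transcripts hp001.. ; the first n_double carry two
  # sites (all functional), then single-site transcripts: functional first,
  # then eligible, far, bare.
  ids <- sprintf("hp%03d", seq_len(nT))
  rows <- list()
  motif_i <- 0L
  next_motif <- function() {
    motif_i <<- motif_i + 1L
    motifs[((motif_i - 1L) %% length(motifs)) + 1L]
  }
  for (t in seq_len(n_double))
    for (s in 1:2)
      rows[[length(rows) + 1L]] <- list(tid = ids[t], motif = next_motif(),
                                        kind = "functional")
  n_fun_single <- nF - 2L * n_double
  kinds <- c(rep("functional", n_fun_single), rep("eligible", nE),
             rep("far", nFar),
             rep("bare", (nP - nF - nE - nFar)))
  for (k in seq_along(kinds))
    rows[[length(rows) + 1L]] <- list(tid = ids[n_double + k],
                                      motif = next_motif(), kind = kinds[k])

  db <- list()
  truth_rows <- list()
  dist_i <- 0L
  site_types <- c("Drosha", "Dicer")
  for (tid in ids) {
    mine <- Filter(function(r) r$tid == tid, rows)
    feats <- list()
    planted_dist <- NA_integer_
    if (length(mine) == 0L) {
      feats <- list()
    } else if (length(mine) == 2L) {
      feats <- list(list(type = "motif", stem_before = 4L,
                         notation = mine[[1L]]$motif),
                    list(type = "motif", stem_before = 3L,
                         notation = mine[[2L]]$motif))
    } else {
      kind <- mine[[1L]]$kind
      if (kind %in% c("eligible", "far")) {
        d <- if (kind == "eligible") {
          dist_i <- dist_i + 1L
          plan$eligible_distances[((dist_i - 1L) %%
                                     length(plan$eligible_distances)) + 1L]
        } else plan$far_distance
        planted_dist <- d
        # unn interior at depth 5; motif interior must sit at depth 5+d+1
        feats <- list(list(type = "unn", stem_before = 4L),
                      list(type = "motif", stem_before = d - 1L,
                           notation = mine[[1L]]$motif))
      } else {
        feats <- list(list(type = "motif", stem_before = 4L,
                           notation = mine[[1L]]$motif))
      }
    }
    built <- build_hairpin(tid, feats)
    placed_motifs <- Filter(function(p) p$type == "motif", built$placed)
    placed_unn <- Filter(function(p) p$type == "unn", built$placed)
    ann <- data.frame(site_type = "Drosha", position = 2L,
                      stringsAsFactors = FALSE)
    for (k in seq_along(mine)) {
      p <- placed_motifs[[k]]
      functional <- mine[[k]]$kind == "functional"
      if (functional)
        ann <- rbind(ann, data.frame(
          site_type = site_types[(k %% 2L) + 1L], position = p$top_start,
          stringsAsFactors = FALSE))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transcript_id = tid, motif = mine[[k]]$motif, kind = mine[[k]]$kind,
        functional = functional,
        top_start = p$top_start, top_end = p$top_end,
        bottom_start = p$bottom_start, bottom_end = p$bottom_end,
        unn_pos = if (length(placed_unn)) placed_unn[[1L]]$u_pos
                  else NA_integer_,
        planted_distance = if (mine[[k]]$kind %in% c("eligible", "far"))
          planted_dist else NA_integer_,
        eligible = mine[[k]]$kind == "eligible", stringsAsFactors = FALSE)
    }
    db[[tid]] <- hairpin_structure(tid, built$structure$seq,
                                   built$structure$db, annotations = ann)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(db = db,
       truth = list(placements = truth, plan = plan, seed = seed,
                    generator = .RNG_ID))
}

# ---- synthetic compounds ---------------------------------------------------

.TEMPLATES_DEFAULT <- c(benzene = "c1ccccc1", cyclohexane = "C1CCCCC1",
                        pyridine = "c1ccncc1",
                        naphthalene = "c1ccc2ccccc2c1",
                        thiophene = "c1ccsc1")

.DECORATIONS <- c("C", "CC", "CCC", "CCCC", "CO", "CCO", "CCCO", "CN", "CCN",
                  "CCCN", "COC", "CCOC", "CNC", "CCNC", "OC", "OCC", "NC",
                  "NCC", "OCCC", "NCCC", "O", "N", "CC(C)", "CC(C)C",
                  "OCC(C)")

#' Generate synthetic compound sets from fragment templates
#'
#' Each compound is a ring-system template decorated with an acyclic
#' substituent, so template membership is the scaffold ground truth.
#'
#' @param n_per_template Decorated compounds per template.
#' @param templates Named character vector of ring-system SMILES accepting a
#'   substituent prefix.
#' @param seed Integer seed.
#' @return List `compounds` (data frame `compound_id`, `smiles`,
#'   `template`) and `truth`.
#' @export
gen_compounds <- function(n_per_template = 20L,
                          templates = .TEMPLATES_DEFAULT, seed = 1L) {
  if (n_per_template < 0L) stop("invalid n_per_template", call. = FALSE)
  if (n_per_template > length(.DECORATIONS))
    stop("at most ", length(.DECORATIONS), " decorations per template",
         call. = FALSE)
  if (n_per_template == 0L || !length(templates))
    return(list(compounds = data.frame(compound_id = character(0),
                                       smiles = character(0),
                                       template = character(0),
                                       stringsAsFactors = FALSE),
                truth = list(seed = seed, generator = .RNG_ID)))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  rows <- list()
  for (t in names(templates)) {
    dec <- sample(.DECORATIONS, n_per_template)
    rows[[t]] <- data.frame(
      compound_id = sprintf("%s_%02d", t, seq_len(n_per_template)),
      smiles = paste0(dec, templates[[t]]), template = t,
      stringsAsFactors = FALSE)
  }
  compounds <- do.call(rbind, rows)
  rownames(compounds) <- NULL
  # validate: every SMILES must parse
  invisible(.parse_smiles_set(compounds$smiles, compounds$compound_id))
  list(compounds = compounds,
       truth = list(templates = templates, seed = seed, generator = .RNG_ID))
}
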