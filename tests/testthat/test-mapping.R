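# Transcriptome mapping and functional-site annotation.

make_db_with_bulge <- function(n_total = 10L, n_with = 3L, seed = 2L) {
  set.seed(seed)
  db <- list()
  for (i in seq_len(n_total)) {
    feats <- if (i <= n_with)
      list(list(type = "motif", stem_before = 4L, notation = "5'GAC/3'C_G"))
    else list()
    b <- build_hairpin(sprintf("hp%02d", i), feats)
    db[[b$structure$id]] <- b$structure
  }
  db
}

test_that("the motif index keys by canonical identity", {
  expect_equal(nrow(build_motif_index(list())), 0L)

  db <- make_db_with_bulge()
  idx <- build_motif_index(db)
  key <- motif_key("5'GAC/3'C_G")
  expect_equal(sum(idx$key == key), 3L)
  # strand-swapped writing collides onto the same key
  expect_equal(motif_key("5'G_C/3'CAG"), key)
})

test_that("map_binders counts sites, transcripts and multiplicity", {
  db <- make_db_with_bulge()
  idx <- build_motif_index(db)
  none <- map_binders(data.frame(compound_id = "C9",
                                 motif = "5'GGC/3'CGG"), idx)
  expect_equal(nrow(none), 0L)

  hits <- map_binders(data.frame(compound_id = "C1",
                                 motif = "5'G_C/3'CAG"), idx)
  expect_equal(nrow(hits), 3L)
  expect_equal(attr(hits, "n_transcripts"), 3L)
  expect_equal(attr(hits, "n_motifs"), 1L)

  # one motif planted twice in one hairpin: 2 sites, 1 transcript
  set.seed(4)
  b <- build_hairpin("twice", list(
    list(type = "motif", stem_before = 3L, notation = "5'GAC/3'C_G"),
    list(type = "motif", stem_before = 3L, notation = "5'GAC/3'C_G")))
  idx2 <- build_motif_index(list(twice = b$structure))
  h2 <- map_binders(data.frame(compound_id = "C1", motif = "5'GAC/3'C_G"),
                    idx2)
  expect_equal(nrow(h2), 2L)
  expect_equal(attr(h2, "n_sites"), 2L)
  expect_equal(attr(h2, "n_transcripts"), 1L)
})

test_that("functional annotation applies the +/- window around scissile positions", {
  set.seed(6)
  b <- build_hairpin("f1", list(list(type = "motif", stem_before = 4L,
                                     notation = "5'GAC/3'C_G")))
  p <- b$placed[[1]]
  span_min <- p$top_start
  for (d in c(0L, 2L, 3L)) {
    hs <- hairpin_structure("f1", b$structure$seq, b$structure$db,
                            annotations = data.frame(
                              site_type = "Dicer",
                              position = span_min - d))
    db <- list(f1 = hs)
    sites <- map_binders(data.frame(compound_id = "C1",
                                    motif = "5'GAC/3'C_G"),
                         build_motif_index(db))
    ann <- annotate_functional(sites, db, window = 2L)
    expect_equal(ann$functional, d <= 2L)
    expect_equal(ann$nearest_processing_distance, d)
  }
  # no annotations at all: silent and flagged unannotated
  db0 <- list(f1 = b$structure)
  sites <- map_binders(data.frame(compound_id = "C1",
                                  motif = "5'GAC/3'C_G"),
                       build_motif_index(db0))
  ann0 <- annotate_functional(sites, db0)
  expect_false(ann0$functional)
  expect_true(ann0$unannotated)
})

test_that("targetability summaries recompute exactly from counts", {
  s0 <- summarize_targetability(data.frame())
  expect_equal(s0$n_sites, 0L)
  expect_equal(s0$pct_functional, 0)

  fake <- data.frame(
    site_id = sprintf("s%03d", 1:114),
    transcript_id = sprintf("t%03d", c(1:111, 1:3)),
    functional = rep(c(TRUE, FALSE), c(33, 81)),
    rnasel_eligible = rep(c(FALSE, TRUE, FALSE), c(33, 55, 26)))
  s <- summarize_targetability(fake)
  expect_equal(s$n_sites, 114L)
  expect_equal(s$n_functional, 33L)
  expect_equal(s$n_silent, 81L)
  expect_equal(s$pct_functional, 28.9)
  expect_equal(s$pct_rnasel_eligible, 48.2)
  expect_equal(s$pct_functional,
               floor(1000 * 33 / 114 + 0.5) / 10)  # bit-exact recompute
  expect_equal(s$n_functional + s$n_silent, s$n_sites)
})

test_that("structure databases round-trip through dot-bracket and TSV files", {
  set.seed(8)
  g <- gen_structure_db(plan = local({
    p <- triage_plan_default()
    p$n_transcripts <- 6L; p$n_placements <- 7L; p$n_functional <- 3L
    p$n_eligible <- 2L; p$n_far <- 1L
    p
  }), seed = 3)
  dbn <- tempfile(fileext = ".dbn"); ann <- tempfile(fileext = ".tsv")
  write_structure_db(g$db, dbn, ann)
  back <- read_structure_db(dbn, ann)
  expect_equal(names(back), names(g$db))
  for (id in names(g$db)) {
    expect_equal(back[[id]]$seq, g$db[[id]]$seq)
    expect_equal(back[[id]]$db, g$db[[id]]$db)
    expect_equal(back[[id]]$annotations$position,
                 g$db[[id]]$annotations$position)
  }
})
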