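# Synthetic-data generators: determinism and planted ground truth.

test_that("gen_selection is deterministic and respects the pool model", {
  a <- gen_selection(500, c(M00001 = 10), depth_sel = 2e4, depth_in = 2e4,
                     seed = 42)
  b <- gen_selection(500, c(M00001 = 10), depth_sel = 2e4, depth_in = 2e4,
                     seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a$counts$k_sel), 2e4)
  expect_equal(sum(a$counts$k_in), 2e4)
  c2 <- gen_selection(500, c(M00001 = 10), depth_sel = 2e4, depth_in = 2e4,
                      seed = 43)
  expect_false(identical(a$counts, c2$counts))
  expect_error(gen_selection(0, numeric(0)), "invalid")
  expect_error(gen_selection(10, c(M00001 = -1)), ">= 0")
  expect_error(gen_selection(10, c(ZZZ = 2)), "universe")
})

test_that("under the null the z statistics are approximately standard normal", {
  g <- gen_selection(2000, numeric(0), depth_sel = 1e4, depth_in = 1e4,
                     seed = 5)
  z <- zobs_table(g$counts)$zobs
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(stats::sd(z) - 1), 0.1)
  # KS distance to N(0,1) small (the counts are discrete, so only
  # approximate agreement is expected)
  d <- suppressWarnings(stats::ks.test(z, "pnorm")$statistic)
  expect_lt(unname(d), 0.12)
})

test_that("the generators do not write to the session RNG state", {
  set.seed(123); before <- .Random.seed
  invisible(gen_selection(100, numeric(0), seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("a feature-free plan yields perfect hairpins only", {
  p <- triage_plan_default()
  p$n_transcripts <- 4L; p$n_placements <- 0L; p$n_functional <- 0L
  p$n_eligible <- 0L; p$n_far <- 0L
  g <- gen_structure_db(plan = p, seed = 2)
  expect_equal(length(g$db), 4L)
  for (s in g$db) {
    mot <- extract_motifs(s)
    expect_equal(mot$motif_class, "hairpin loop")
    expect_equal(nrow(scan_rnasel(s)), 0L)
  }
})

test_that("found features equal planted features across seeds", {
  p <- triage_plan_default()
  p$n_transcripts <- 20L; p$n_placements <- 22L; p$n_functional <- 6L
  p$n_eligible <- 8L; p$n_far <- 3L
  for (seed in c(1, 7)) {
    g <- gen_structure_db(plan = p, seed = seed)
    tr <- g$truth$placements
    expect_equal(nrow(tr), 22L)
    idx <- build_motif_index(g$db)
    # every planted placement is recovered at its recorded span
    for (i in seq_len(nrow(tr))) {
      hit <- idx[idx$transcript_id == tr$transcript_id[i] &
                   idx$top_start == tr$top_start[i], ]
      expect_equal(nrow(hit), 1L)
      expect_equal(hit$key, motif_key(tr$motif[i]))
    }
    # no spurious binding-motif hits: indexed planted keys match count
    planted_keys <- vapply(tr$motif, motif_key, character(1))
    expect_equal(sum(idx$key %in% planted_keys), nrow(tr))
    # scanner finds exactly the planted cleavage loops
    for (id in names(g$db)) {
      found <- scan_rnasel(g$db[[id]])$start
      planted <- tr$unn_pos[tr$transcript_id == id]
      planted <- unique(planted[!is.na(planted)])
      expect_equal(sort(found), sort(planted))
    }
    # planted stem distances are reproduced by the distance operation
    el <- tr[!is.na(tr$planted_distance), ]
    for (i in seq_len(nrow(el))) {
      s <- g$db[[el$transcript_id[i]]]
      span <- c(el$top_start[i]:el$top_end[i],
                el$bottom_start[i]:el$bottom_end[i])
      expect_equal(stem_distance(s, span, el$unn_pos[i]),
                   el$planted_distance[i])
    }
  }
})

test_that("structure generation is byte-identical under the same seed", {
  p <- triage_plan_default()
  p$n_transcripts <- 8L; p$n_placements <- 9L; p$n_functional <- 3L
  p$n_eligible <- 3L; p$n_far <- 1L
  g1 <- gen_structure_db(plan = p, seed = 11)
  g2 <- gen_structure_db(plan = p, seed = 11)
  f1 <- tempfile(); f2 <- tempfile()
  write_structure_db(g1$db, f1)
  write_structure_db(g2$db, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(gen_structure_db(plan = local({
    q <- triage_plan_default(); q$n_functional <- 200L; q
  })), "infeasible")
})

test_that("compound generation produces valid, template-faithful sets", {
  g0 <- gen_compounds(0)
  expect_equal(nrow(g0$compounds), 0L)
  g <- gen_compounds(20, seed = 8)
  expect_equal(nrow(g$compounds), 100L)
  expect_identical(g, gen_compounds(20, seed = 8))
  sc <- scaffold_classes(setNames(g$compounds$smiles,
                                  g$compounds$compound_id))
  expect_equal(attr(sc, "n_scaffolds"), 5L)
  # scaffold assignment is constant within a template (decoration
  # invariance) and distinct across templates
  tab <- table(sc$scaffold_id, g$compounds$template)
  expect_true(all(colSums(tab > 0) == 1))
  expect_equal(sum(tab > 0), 5L)
})
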