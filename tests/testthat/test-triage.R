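# RNase L scanning, stem distances and RIBOTAC triage.

test_that("a fully paired stem with a U-free loop has no substrate sites", {
  hs <- hairpin_structure("d1", "GGGGGGGGGCAACCCCCCCC",
                          "((((((((....))))))))")
  expect_equal(nrow(scan_rnasel(hs)), 0L)
})

test_that("the asymmetric pyrimidine loop is reported as a substrate", {
  # the 1x2 loop context of the miR-155 cleavage site: 5'UUU/3'GUCA with
  # unpaired Us on both strands
  set.seed(12)
  b <- build_hairpin("m155", list(list(type = "motif", stem_before = 4L,
                                       notation = "5'UUU/3'GUCA")))
  sites <- scan_rnasel(b$structure)
  expect_gt(nrow(sites), 0L)
  expect_true(all(substr(sites$trinucleotide, 1, 1) == "U"))
  expect_true(any(grepl("internal loop", sites$loop_context)))
  # strict mode (all Us in the window unpaired) only ever drops sites
  strict <- scan_rnasel(b$structure, strict = TRUE)
  expect_true(all(strict$start %in% sites$start))
})

test_that("exactly the planted UNN loops are found, at exact positions", {
  set.seed(13)
  for (seed in 1:3) {
    set.seed(seed)
    b <- build_hairpin("u2", list(
      list(type = "unn", stem_before = 3L),
      list(type = "unn", stem_before = 4L),
      list(type = "motif", stem_before = 3L, notation = "5'GAC/3'CAG")))
    planted <- vapply(Filter(function(p) p$type == "unn", b$placed),
                      function(p) p$u_pos, integer(1))
    found <- scan_rnasel(b$structure)$start
    expect_equal(sort(found), sort(planted))
  }
})

test_that("stem distance counts intervening base pairs", {
  # adjacency: unpaired U immediately inside the motif's closing pair
  set.seed(15)
  b0 <- build_hairpin("adj", list(list(type = "motif", stem_before = 4L,
                                       notation = "5'GAC/3'C_G")),
                      stem_after = 0L, apical = "UGCA")
  sc0 <- scan_rnasel(b0$structure)
  expect_equal(nrow(sc0), 1L)
  p <- b0$placed[[1]]
  span0 <- c(p$top_start:p$top_end, p$bottom_start:p$bottom_end)
  expect_equal(stem_distance(b0$structure, span0, sc0$start[1]), 0L)

  # seven base pairs between an A bulge and the cleavage loop, mirroring
  # the miR-155 geometry
  b7 <- build_hairpin("mir155like", list(
    list(type = "unn", stem_before = 4L),
    list(type = "motif", stem_before = 6L, notation = "5'GAC/3'C_G")))
  p <- Filter(function(q) q$type == "motif", b7$placed)[[1]]
  u <- Filter(function(q) q$type == "unn", b7$placed)[[1]]
  span <- c(p$top_start:p$top_end, p$bottom_start:p$bottom_end)
  expect_equal(stem_distance(b7$structure, span, u$u_pos), 7L)

  # monotonicity along one stem: farther loops never get smaller distances
  bmulti <- build_hairpin("mono", list(
    list(type = "motif", stem_before = 3L, notation = "5'GAC/3'C_G"),
    list(type = "unn", stem_before = 2L),
    list(type = "unn", stem_before = 2L),
    list(type = "unn", stem_before = 2L)))
  pm <- bmulti$placed[[1]]
  spanm <- c(pm$top_start:pm$top_end, pm$bottom_start:pm$bottom_end)
  us <- Filter(function(q) q$type == "unn", bmulti$placed)
  dd <- vapply(us, function(q)
    stem_distance(bmulti$structure, spanm, q$u_pos), integer(1))
  expect_true(all(diff(dd) > 0))
})

test_that("triage accepts within 10 bp inclusive and rejects beyond", {
  set.seed(16)
  db <- list(); want <- c()
  for (d in c(3L, 10L, 11L)) {
    id <- sprintf("d%02d", d)
    b <- build_hairpin(id, list(
      list(type = "unn", stem_before = 4L),
      list(type = "motif", stem_before = d - 1L, notation = "5'GAC/3'C_G")))
    db[[id]] <- b$structure
    want <- c(want, d <= 10L)
  }
  sites <- map_binders(data.frame(compound_id = "C1", motif = "5'GAC/3'C_G"),
                       build_motif_index(db))
  sites <- annotate_functional(sites, db)   # no annotations: all silent
  tri <- triage_candidates(sites, db, max_distance = 10L)
  tri <- tri[order(tri$transcript_id), ]
  expect_equal(tri$stem_distance_bp, c(3L, 10L, 11L))
  expect_equal(tri$rnasel_eligible, c(TRUE, TRUE, FALSE))
  expect_equal(tri$triage_flag,
               c("ribotac-candidate", "ribotac-candidate",
                 "cleavage-too-far"))
})

test_that("sites without any cleavage option or with functional flags pass through", {
  set.seed(17)
  b <- build_hairpin("bare", list(list(type = "motif", stem_before = 4L,
                                       notation = "5'GAC/3'C_G")))
  db <- list(bare = b$structure)
  sites <- map_binders(data.frame(compound_id = "C1", motif = "5'GAC/3'C_G"),
                       build_motif_index(db))
  sites <- annotate_functional(sites, db)
  tri <- triage_candidates(sites, db)
  expect_false(tri$rnasel_eligible)
  expect_equal(tri$triage_flag, "no-cleavage-site")
  expect_true(is.na(tri$stem_distance_bp))

  # functional site: bioactive by binding, not triaged against RNase L
  hs <- hairpin_structure("bare", b$structure$seq, b$structure$db,
                          annotations = data.frame(
                            site_type = "Drosha",
                            position = b$placed[[1]]$top_start))
  db2 <- list(bare = hs)
  s2 <- annotate_functional(
    map_binders(data.frame(compound_id = "C1", motif = "5'GAC/3'C_G"),
                build_motif_index(db2)), db2)
  t2 <- triage_candidates(s2, db2)
  expect_true(t2$functional)
  expect_equal(t2$triage_flag, "bioactive-by-binding")
  expect_true(is.na(t2$rnasel_eligible))
})
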