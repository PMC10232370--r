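# Enrichment statistics: Z_obs, bound calls, LOGO matrices, class tests.

test_that("zobs matches the pooled two-proportion oracle and its symmetries", {
  expect_equal(zobs(50, 1000, 50, 1000), 0)
  expect_equal(zobs(0, 1000, 0, 1000), 0)     # degenerate pooled proportion
  expect_equal(zobs(1000, 1000, 1000, 1000), 0)

  set.seed(21)
  for (i in 1:50) {
    n1 <- sample(100:5000, 1); n2 <- sample(100:5000, 1)
    k1 <- rbinom(1, n1, 0.02); k2 <- rbinom(1, n2, 0.02)
    expect_equal(zobs(k1, n1, k2, n2), oracle_pooled_z(k1, n1, k2, n2),
                 tolerance = 1e-12)
    # antisymmetry under pool swap
    expect_equal(zobs(k1, n1, k2, n2), -zobs(k2, n2, k1, n1),
                 tolerance = 1e-12)
  }
  expect_equal(zobs(30, 1000, 10, 1000), oracle_pooled_z(30, 1000, 10, 1000),
               tolerance = 1e-12)

  expect_error(zobs(1, 0, 1, 10), "depth")
  expect_error(zobs(11, 10, 1, 10), "0 <= k <= n")
})

test_that("zobs agrees with the normal approximation of the permutation null", {
  # permutation null for fixed margins is hypergeometric in k_sel
  k1 <- 30; n1 <- 1000; k2 <- 10; n2 <- 1000
  K <- k1 + k2
  set.seed(33)
  ks <- stats::rhyper(1e5, K, n1 + n2 - K, n1)
  zstar <- zobs(ks, n1, K - ks, n2)
  expect_lt(abs(mean(zstar)), 0.02)
  expect_lt(abs(stats::sd(zstar) - 1), 0.05)
  # tail beyond 1.96 close to the normal tail, within Monte-Carlo error
  expect_lt(abs(mean(zstar > 1.96) - stats::pnorm(-1.96)), 0.012)
})

test_that("bound calls use a strict one-sided threshold", {
  res <- data.frame(motif_id = c("a", "b", "c"), zobs = c(8.1, 7.9, -12))
  expect_equal(call_bound(res, 8), "a")
  expect_equal(call_bound(data.frame(motif_id = character(0),
                                     zobs = numeric(0))), character(0))
  res2 <- data.frame(motif_id = "x", zobs = 8)
  expect_equal(call_bound(res2, 8), character(0))  # strictly greater than
})

test_that("planted enrichments are recovered as bound", {
  planted <- sprintf("M%05d", 1:20)
  for (seed in 1:5) {
    g <- gen_selection(4096, setNames(rep(10, 20), planted),
                       depth_sel = 1e5, depth_in = 1e5, seed = seed)
    zt <- zobs_table(g$counts)
    bound <- call_bound(zt, 8)
    expect_true(all(planted %in% bound))
  }
})

test_that("logo matrix ranks, retains and normalizes correctly", {
  one <- logo_matrix(data.frame(motif_id = "ACGU", zobs = 10),
                     top_fraction = 1)
  expect_equal(one["A", 1], 1)
  expect_equal(one["U", 4], 1)
  expect_true(all(colSums(one) == 1))

  two <- logo_matrix(data.frame(motif_id = c("AAAA", "CCCC"),
                                zobs = c(5, 5)), top_fraction = 1)
  expect_equal(unname(two["A", ]), rep(0.5, 4))
  expect_equal(unname(two["C", ]), rep(0.5, 4))

  set.seed(7)
  ids <- vapply(1:1000, function(i)
    paste(sample(c("A", "C", "G", "U"), 6, TRUE), collapse = ""),
    character(1))
  z <- stats::runif(1000, 0, 50)
  res <- data.frame(motif_id = ids, zobs = z)
  lm <- logo_matrix(res, top_fraction = 0.005)
  kept <- attr(lm, "motifs")
  expect_equal(length(kept), 5L)  # ceil(0.005 * 1000)
  # the retained set is the top five by z with lexicographic tie-break
  want <- ids[order(-z, ids)][1:5]
  expect_setequal(kept, want)
  # hand-computed column frequencies
  hand <- vapply(1:6, function(j)
    mean(substr(want, j, j) == "A"), numeric(1))
  expect_equal(unname(lm["A", ]), hand)
  expect_true(all(abs(colSums(lm) - 1) < 1e-12))
  expect_error(logo_matrix(res[0, ]), "empty")
})

test_that("class enrichment t-test matches the closed form", {
  bf <- data.frame(`3x3` = c(0.7, 0.8, 0.75), check.names = FALSE)
  out <- class_enrichment(bf, c(`3x3` = 0.48))
  want <- oracle_t(c(0.7, 0.8, 0.75), 0.48)
  expect_equal(out$t, want$t)
  expect_equal(out$p_value, want$p)
  expect_equal(out$direction, "enriched")

  flat <- class_enrichment(data.frame(a = c(0.5, 0.5, 0.5)), c(a = 0.5))
  expect_equal(flat$t, 0)
  expect_equal(flat$p_value, 1)

  single <- class_enrichment(data.frame(a = 0.9), c(a = 0.5))
  expect_true(single$flagged)
  expect_true(is.na(single$p_value))
})

test_that("selections biased toward 3x3 loops flag that class as enriched", {
  lib <- classify_members(enumerate_library())
  bg <- table(lib$motif_class) / nrow(lib)
  set.seed(14)
  # six simulated compounds, each preferring 3x3-loop members
  fracs <- t(vapply(1:6, function(cmp) {
    pref <- ifelse(lib$motif_class == "3×3 internal loop", 8, 1)
    bound_idx <- sample(nrow(lib), 150, prob = pref)
    cl <- lib$motif_class[bound_idx]
    vapply(names(bg), function(k) mean(cl == k), numeric(1))
  }, numeric(length(bg))))
  out <- class_enrichment(as.data.frame(fracs),
                          setNames(as.numeric(bg), names(bg)))
  row <- out[out$motif_class == "3×3 internal loop", ]
  expect_equal(row$direction, "enriched")
  expect_lt(row$p_value, 0.05)
})
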