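# Independent oracles used across the suite; these deliberately avoid the
# package's own code paths.

# Pooled two-proportion z via prop.test's chi-square (no continuity
# correction): z = sign(phi1 - phi2) * sqrt(X^2).
oracle_pooled_z <- function(k1, n1, k2, n2) {
  if (k1 + k2 == 0 || k1 + k2 == n1 + n2) return(0)
  x2 <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE)$statistic)
  unname(sign(k1 / n1 - k2 / n2) * sqrt(x2))
}

# Exhaustive nested-pairing oracle for a randomized region between fixed
# closing pairs. Pairs (i on top, j on bottom-as-written) must be mutually
# nested: i and j both increasing. Returns the classification implied by a
# maximum pairing (case analysis valid for 1+1 and 2+2 regions).
oracle_pairs_ok <- function(x, y) paste0(x, y) %in%
  c("GC", "CG", "AU", "UA", "GU", "UG")

oracle_max_pairing <- function(t, b) {
  t <- strsplit(t, "")[[1]]; b <- strsplit(b, "")[[1]]
  a <- length(t); m <- length(b)
  f <- matrix(0L, a + 1L, m + 1L)
  for (i in seq_len(a)) for (j in seq_len(m))
    f[i + 1L, j + 1L] <- max(f[i, j + 1L], f[i + 1L, j],
                             f[i, j] + oracle_pairs_ok(t[i], b[j]))
  f[a + 1L, m + 1L]
}

oracle_classify_2plus2 <- function(top, bottom) {
  t <- strsplit(top, "")[[1]]; b <- strsplit(bottom, "")[[1]]
  aligned <- c(oracle_pairs_ok(t[1], b[1]), oracle_pairs_ok(t[2], b[2]))
  skew <- c(oracle_pairs_ok(t[1], b[2]), oracle_pairs_ok(t[2], b[1]))
  if (all(aligned)) return("fully paired")
  if (any(aligned)) return("1×1 internal loop")
  if (any(skew)) return("bulge loop")
  "2×2 internal loop"
}

oracle_classify_1plus1 <- function(top, bottom) {
  if (oracle_pairs_ok(top, bottom)) "fully paired" else
    "1×1 internal loop"
}

# Random valid motif generator (canonical-form-agnostic): random closing
# pairs and random interiors with gaps (no gap/gap column).
random_motif_notation <- function(max_interior = 4L) {
  pairs <- c("GC", "CG", "AU", "UA", "GU", "UG")
  nts <- c("A", "C", "G", "U")
  cl <- strsplit(sample(pairs, 1), "")[[1]]
  cr <- strsplit(sample(pairs, 1), "")[[1]]
  k <- sample(0:max_interior, 1)
  top <- character(k); bottom <- character(k)
  for (j in seq_len(k)) {
    repeat {
      x <- sample(c(nts, "_"), 1); y <- sample(c(nts, "_"), 1)
      if (!(x == "_" && y == "_")) break
    }
    top[j] <- x; bottom[j] <- y
  }
  paste0("5'", cl[1], paste(top, collapse = ""), cr[1],
         "/3'", cl[2], paste(bottom, collapse = ""), cr[2])
}

# One-sample two-tailed t-test by the closed form.
oracle_t <- function(x, mu) {
  n <- length(x)
  tt <- (mean(x) - mu) / (stats::sd(x) / sqrt(n))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1))
}
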