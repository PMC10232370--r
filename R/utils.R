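# Small shared helpers.

# Half-up rounding at d decimals (R's round() is half-to-even); this is the
# convention behind printed percentages like 28.9% and 0.22%.
round_half_up <- function(x, d = 0L) {
  s <- 10^d
  floor(x * s + 0.5) / s
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
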