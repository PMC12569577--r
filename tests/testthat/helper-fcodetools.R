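# Shared fixtures and small generators used across test files.

simpsonsPath <- function() {
  system.file("extdata", "simpsons.fdata", package = "fcodetools")
}

# Arbitrary lenient codes, wrong patterns included: stress input for the
# normalizer and parser, independent of the package's own pattern-free
# generator. Caller controls the RNG seed.
randomLenientCode <- function(maxDepth = 6L) {
  syms <- c("P", "M", "X", "C", "O", "A", "H", "o", "a", "h")
  d <- sample(0:maxDepth, 1L)
  parts <- vapply(seq_len(d), function(i) {
    s <- sample(syms, 1L)
    needs <- s %in% c("O", "A", "H", "o", "a", "h")
    ord <- if (needs || stats::runif(1L) < 0.3) {
      if (stats::runif(1L) < 0.15) "?" else as.character(sample(1:4, 1L))
    } else ""
    paste0(s, ord)
  }, character(1L))
  paste0("*", paste0(parts, collapse = ""))
}

# Person-identity comparison up to sex degradation and unrecorded orders:
# same lineage (desexed, number-free) and layer-wise compatible orders.
codesCompatible <- function(a, b) {
  fa <- parseFcode(a)
  fb <- parseFcode(b)
  if (fcodeLineage(fa) != fcodeLineage(fb)) return(FALSE)
  oa <- fa@orders
  ob <- fb@orders
  both <- !is.na(oa) & !is.na(ob)
  all(oa[both] == ob[both])
}
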