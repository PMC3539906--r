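# Shared fixtures and independent oracles for the test suite.

fix_es <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_enzyme_table(mac_enzyme_file())
    cache
  }
})

fix_hybrids <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- hybrid_table(fix_es())
    cache
  }
})

## Independent reverse complement (no Biostrings, no package internals).
naive_revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

## Brute-force scanner oracle: compare every k-window of `s` against every
## word by direct substring equality (vectorised, no regex).
naive_scan <- function(s, words) {
  L <- nchar(s)
  out <- list()
  for (w in words) {
    k <- nchar(w)
    if (L < k) next
    kmers <- substring(s, 1:(L - k + 1), k:L)
    pos <- which(kmers == w)
    if (length(pos)) out[[w]] <- pos
  }
  out
}

## Order a (possibly empty) named list of positions by word, for comparison.
by_word <- function(l) {
  if (!length(l)) return(list())
  lapply(l[order(names(l))], as.integer)
}

## All 4^k k-mers, enumeration oracle.
all_kmers <- function(k) {
  apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                    stringsAsFactors = FALSE), 1, paste, collapse = "")
}

## Poly-A background with motifs planted at given positions: contains no
## fixture site or hybrid word except the plants, so planner tests are
## fully deterministic.
planted_background <- function(L, positions, sequences) {
  plant_sites(strrep("A", L),
              data.frame(position = positions, sequence = sequences,
                         stringsAsFactors = FALSE))
}
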