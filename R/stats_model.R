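# Binomial model of hexamer site occurrence in random DNA, plus a seeded
# Monte Carlo cross-check.
#
# Model: a fixed 6-mer matches an i.i.d. uniform ACGT sequence of length L
# at each of n = L - 6 + 1 window starts with probability p = 4^-6, windows
# treated as independent trials (the overlap correlation is negligible at
# these scales and is quantified by monte_carlo_site_freq()).

SITE_K <- 6L
SITE_P <- 4^-6

n_trials <- function(L) pmax(0, floor(L) - SITE_K + 1L)

check_length <- function(L) {
  if (!is.numeric(L) || any(is.na(L)) || any(L < 0)) {
    stop("fragment length must be non-negative", call. = FALSE)
  }
  L
}

#' Probability that a given hexamer site is absent from a fragment
#'
#' Binomial zero class: `(1 - 4^-6)^(L - 5)`. For a 5000-bp fragment this
#' is 29.5%: about three in ten hexamer cutters cannot be used at all on a
#' fragment that long.
#'
#' @param L fragment length in bp (vectorised, `>= 0`).
#' @return probability in `[0, 1]`.
#' @examples
#' round(prob_no_site(5000), 3)  # 0.295
#' @export
prob_no_site <- function(L) {
  (1 - SITE_P)^n_trials(check_length(L))
}

#' Probability of two or more occurrences of a given hexamer site
#'
#' `1 - P(0) - P(1)` under the binomial model; 34.4% for a 5000-bp
#' fragment, so multi-cutters are as common as non-cutters at that scale.
#'
#' @inheritParams prob_no_site
#' @return probability in `[0, 1]`.
#' @examples
#' round(prob_multi_site(5000), 3)  # 0.344
#' @export
prob_multi_site <- function(L) {
  n <- n_trials(check_length(L))
  pmax(0, 1 - (1 - SITE_P)^n - n * SITE_P * (1 - SITE_P)^pmax(0, n - 1))
}

#' Probability of at least one occurrence within a module
#'
#' The chance that the recognition site of a junction enzyme also occurs
#' inside the module it is meant to flank -- the one limitation on using
#' hybrid sites. `method = "exact"` gives `1 - (1-p)^n`; `"linear"` gives
#' the expected-count bound `min(1, L * 4^-6)` (the union bound, always >=
#' exact), which rounds to the familiar 25% for 1000-bp and 12.5% for
#' 500-bp modules.
#'
#' @inheritParams prob_no_site
#' @param method `"exact"` or `"linear"`.
#' @return probability in `[0, 1]`.
#' @examples
#' prob_at_least_one(1000, "linear")  # 0.2441...
#' @export
prob_at_least_one <- function(L, method = c("exact", "linear")) {
  method <- match.arg(method)
  check_length(L)
  switch(method,
         exact = 1 - (1 - SITE_P)^n_trials(L),
         linear = pmin(1, L * SITE_P))
}

#' Expected spacing between members of a site family
#'
#' With `n` distinct hexamer sequences in play, some member is expected
#' once every `4^6 / n` bp of random DNA: 64 bp for the 64 palindromes,
#' 16 bp for the 256 hybrid sites -- a four-fold denser grid of candidate
#' junctions.
#'
#' @param n_distinct_sites number of distinct 6-mer sequences (`>= 1`).
#' @return expected bp per occurrence.
#' @examples
#' expected_spacing(256)  # 16
#' @export
expected_spacing <- function(n_distinct_sites) {
  if (!is.numeric(n_distinct_sites) || any(is.na(n_distinct_sites)) ||
      any(n_distinct_sites < 1)) {
    stop("`n_distinct_sites` must be >= 1", call. = FALSE)
  }
  4^6 / n_distinct_sites
}

#' Monte Carlo site-occurrence fractions in random DNA
#'
#' Generates `n_sequences` i.i.d. uniform ACGT sequences of length `L`,
#' counts all (overlapping) occurrences of `site` in each, and returns the
#' fractions with zero and with two or more occurrences. Bit-reproducible
#' for a given seed; the caller's RNG stream is left untouched.
#'
#' @param n_sequences number of replicate sequences (`>= 1`).
#' @param L sequence length in bp (`>= 0`).
#' @param site the 6-mer to count.
#' @param seed integer seed.
#' @return list with `absence`, `multi`, `n_sequences`, `L`.
#' @examples
#' monte_carlo_site_freq(200, 1000, "GAATTC", seed = 1)$absence
#' @export
monte_carlo_site_freq <- function(n_sequences, L, site, seed) {
  if (!is.numeric(n_sequences) || length(n_sequences) != 1L || n_sequences < 1) {
    stop("`n_sequences` must be >= 1", call. = FALSE)
  }
  check_length(L)
  stopifnot(length(L) == 1L)
  site <- toupper(site)
  check_dna(site, "site")
  if (!nzchar(site)) stop("`site` must be non-empty", call. = FALSE)
  n_sequences <- as.integer(n_sequences)
  L <- as.integer(L)
  if (L < nchar(site)) {
    return(list(absence = 1, multi = 0, n_sequences = n_sequences, L = L))
  }
  counts <- with_seed(seed, {
    seqs <- vapply(seq_len(n_sequences), function(i) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, "")
    Biostrings::vcountPattern(site, Biostrings::DNAStringSet(seqs))
  })
  list(absence = mean(counts == 0L), multi = mean(counts >= 2L),
       n_sequences = n_sequences, L = L)
}

#' Tabulate site-occurrence probabilities for a set of fragment lengths
#'
#' @param lengths numeric vector of fragment lengths in bp.
#' @return data frame with columns `L`, `p_no_site`, `p_single`, `p_multi`
#'   (rows sum to 1).
#' @export
site_stats_table <- function(lengths) {
  check_length(lengths)
  n <- n_trials(lengths)
  data.frame(L = lengths,
             p_no_site = prob_no_site(lengths),
             p_single = n * SITE_P * (1 - SITE_P)^pmax(0, n - 1),
             p_multi = prob_multi_site(lengths))
}
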