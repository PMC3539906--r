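# Compatible-overhang classes, hybrid ligation sites and the theoretical
# site-space enumerations.

#' Is a DNA string palindromic (equal to its reverse complement)?
#'
#' @param x character vector of even-length A/C/G/T strings; the empty
#'   string is vacuously palindromic.
#' @return logical vector.
#' @examples
#' is_palindrome(c("GGATCC", "CCATGT"))  # TRUE FALSE
#' @export
is_palindrome <- function(x) {
  stopifnot(is.character(x))
  if (any(is.na(x))) stop("NA sequence", call. = FALSE)
  if (any(grepl("[^ACGT]", x))) {
    stop("sequence contains a non-ACGT symbol", call. = FALSE)
  }
  if (any(nchar(x) %% 2L != 0L)) {
    stop("palindromicity is defined for even-length sequences only", call. = FALSE)
  }
  x == revcomp(x)
}

#' Group hybrid-eligible enzymes into compatible-overhang classes
#'
#' Enzymes leaving identical 4-base 5' overhangs (isocaudomers) can ligate
#' to one another; each class of two or more members yields usable hybrid
#' sites. Enzymes with 3' or blunt ends never appear.
#'
#' @param enzymes an `enzyme_set`.
#' @return data frame (class `compat_classes`) with columns `overhang`,
#'   list-column `members`, `n_members` and `n_pairs` (unordered pairs),
#'   sorted by overhang.
#' @examples
#' cc <- compat_classes(read_enzyme_table(mac_enzyme_file()))
#' cc[cc$overhang == "CATG", "n_members"]  # NcoI + PciI
#' @export
compat_classes <- function(enzymes) {
  stopifnot(inherits(enzymes, "enzyme_set"))
  el <- enzymes[enzymes$hybrid_eligible, , drop = FALSE]
  overs <- sort(unique(el$overhang))
  members <- lapply(overs, function(o) sort(el$name[el$overhang == o]))
  out <- data.frame(overhang = overs,
                    n_members = lengths(members),
                    stringsAsFactors = FALSE)
  out$members <- members
  out$n_pairs <- choose(out$n_members, 2)
  out <- out[, c("overhang", "members", "n_members", "n_pairs")]
  class(out) <- c("compat_classes", "data.frame")
  out
}

#' Construct the hybrid site formed by ligating two compatible enzymes
#'
#' Ligating the cohesive end left by `left` (on the upstream fragment) to
#' the end left by `right` (downstream) regenerates the shared 4-base
#' overhang flanked by the outer bases of the two parent sites:
#' `left.site[1] + overhang + right.site[6]`. For distinct parents the
#' result is non-palindromic and cut by neither; the identity pair
#' regenerates the native site.
#'
#' @param left,right enzyme names or one-row enzyme records; both must be
#'   hybrid-eligible (5', 4-base overhang) and share the same overhang.
#' @param enzymes an `enzyme_set`, required when names are given.
#' @return list (class `hybrid_site`) with elements `left`, `right`,
#'   `sequence`, `overhang`, `is_palindromic`.
#' @examples
#' es <- read_enzyme_table(mac_enzyme_file())
#' hybrid_site("NcoI", "PciI", es)$sequence  # "CCATGT"
#' @export
hybrid_site <- function(left, right, enzymes = NULL) {
  l <- as_enzyme(left, enzymes)
  r <- as_enzyme(right, enzymes)
  for (e in list(l, r)) {
    if (!e$hybrid_eligible) {
      stop(sprintf("enzyme %s is not hybrid-eligible (%s end, overhang '%s')",
                   e$name, e$end_type, e$overhang), call. = FALSE)
    }
  }
  if (l$overhang != r$overhang) {
    stop(sprintf("incompatible overhangs: %s leaves %s, %s leaves %s",
                 l$name, l$overhang, r$name, r$overhang), call. = FALSE)
  }
  seqn <- paste0(substr(l$site, 1, 1), l$overhang, substr(r$site, 6, 6))
  structure(list(left = l$name, right = r$name, sequence = seqn,
                 overhang = l$overhang,
                 is_palindromic = unname(is_palindrome(seqn))),
            class = "hybrid_site")
}

#' All ordered hybrid pairs of an enzyme set
#'
#' One row per ordered pair (left, right) of distinct compatible
#' hybrid-eligible enzymes. Identity pairs regenerate the native
#' palindromic site and are reported as palindromic sites by the scanner,
#' not listed here. Both orientations are present: the sequence of
#' (A, B) is the reverse complement of the sequence of (B, A), so
#' forward-strand scanning of all ordered pairs covers both genomic
#' strands.
#'
#' @param enzymes an `enzyme_set`.
#' @return data frame with columns `left`, `right`, `overhang`,
#'   `sequence`, `is_palindromic` (all `FALSE` here).
#' @export
hybrid_table <- function(enzymes) {
  cc <- compat_classes(enzymes)
  rows <- list()
  for (i in seq_len(nrow(cc))) {
    mem <- cc$members[[i]]
    if (length(mem) < 2L) next
    for (a in mem) for (b in mem) {
      if (a == b) next
      h <- hybrid_site(a, b, enzymes)
      rows[[length(rows) + 1L]] <- data.frame(
        left = a, right = b, overhang = h$overhang,
        sequence = h$sequence, is_palindromic = h$is_palindromic,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(left = character(0), right = character(0),
                      overhang = character(0), sequence = character(0),
                      is_palindromic = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$sequence, out$left, out$right), , drop = FALSE]
}

#' Enumerate the theoretical site spaces
#'
#' Three exhaustive enumerations over the DNA alphabet:
#' \describe{
#'   \item{`palindromes`}{all 6-mers equal to their reverse complement:
#'     the first three bases are free, so there are 4^3 = 64.}
#'   \item{`hybrids_incl_palindromes`}{all 6-mers whose central 4-mer is
#'     palindromic -- everything reachable by ligating 4-base 5' cohesive
#'     ends of (hypothetical) hexamer cutters, palindromes included:
#'     4^2 x 4^2 = 256.}
#'   \item{`palindromic_overhangs`}{all self-reverse-complementary 4-mers:
#'     4^2 = 16.}
#' }
#'
#' @param mode one of `"palindromes"`, `"hybrids_incl_palindromes"`,
#'   `"palindromic_overhangs"`.
#' @return list with elements `mode`, `count` and sorted character vector
#'   `sites`.
#' @examples
#' enumerate_theoretical_sites("palindromes")$count  # 64
#' @export
enumerate_theoretical_sites <- function(mode = c("palindromes",
                                                 "hybrids_incl_palindromes",
                                                 "palindromic_overhangs")) {
  mode <- match.arg(mode)
  mers <- function(k) {
    apply(expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE),
          1L, paste, collapse = "")
  }
  sites <- switch(mode,
    palindromes = {
      half <- mers(3)
      paste0(half, revcomp(half))
    },
    palindromic_overhangs = {
      half <- mers(2)
      paste0(half, revcomp(half))
    },
    hybrids_incl_palindromes = {
      centre <- paste0(mers(2), revcomp(mers(2)))
      outer <- expand.grid(a = DNA_BASES, m = centre, b = DNA_BASES,
                           stringsAsFactors = FALSE)
      paste0(outer$a, outer$m, outer$b)
    })
  sites <- sort(unique(sites))
  list(mode = mode, count = length(sites), sites = sites)
}

#' @export
print.hybrid_site <- function(x, ...) {
  cat(sprintf("<hybrid_site> %s + %s -> %s%s\n", x$left, x$right, x$sequence,
              if (x$is_palindromic) " (palindromic)" else ""))
  invisible(x)
}
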