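# Seeded synthetic-sequence generation: uniform random DNA, motif planting,
# site scrubbing, and builders for plannable targets and worked-example
# surrogates. Everything is deterministic in (parameters, seed) and leaves
# the caller's RNG stream untouched.

#' Random uniform DNA sequence
#'
#' i.i.d. uniform A/C/G/T of length `L`; the null model under which the
#' binomial site statistics hold.
#'
#' @param L length in bp (`>= 0`).
#' @param seed integer seed; identical `(L, seed)` gives identical output.
#' @return a `clean_sequence`.
#' @examples
#' identical(random_sequence(100, 42)$residues,
#'           random_sequence(100, 42)$residues)  # TRUE
#' @export
random_sequence <- function(L, seed) {
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L < 0) {
    stop("`L` must be a single non-negative number", call. = FALSE)
  }
  L <- as.integer(L)
  res <- if (L == 0L) "" else with_seed(seed, {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  })
  structure(list(residues = res,
                 source_name = sprintf("random_L%d_seed%d", L, as.integer(seed))),
            class = "clean_sequence")
}

#' Plant motifs at fixed positions in a sequence
#'
#' Overwrites the bases at each `position .. position + nchar(sequence) - 1`
#' span with the given motif; all other bases are unchanged. Spans must be
#' in bounds and mutually non-overlapping.
#'
#' @param seq a `clean_sequence` or raw text.
#' @param plants data frame with columns `position` (1-based) and
#'   `sequence` (ACGT motif, typically a 6-mer).
#' @return a `clean_sequence` with the motifs written in.
#' @export
plant_sites <- function(seq, plants) {
  cs <- as_clean_sequence(seq)
  if (is.null(plants) || nrow(plants) == 0L) return(cs)
  stopifnot(is.data.frame(plants), all(c("position", "sequence") %in% names(plants)))
  s <- cs$residues
  pos <- as.integer(plants$position)
  seqs <- toupper(plants$sequence)
  for (sq in seqs) check_dna(sq, "planted motif")
  ends <- pos + nchar(seqs) - 1L
  if (any(pos < 1L) || any(ends > nchar(s))) {
    stop("planted span out of bounds", call. = FALSE)
  }
  o <- order(pos)
  if (any(pos[o][-1L] <= ends[o][-length(o)])) {
    i <- which(pos[o][-1L] <= ends[o][-length(o)])[1L]
    stop(sprintf("plants at %d and %d overlap", pos[o][i], pos[o][i + 1L]),
         call. = FALSE)
  }
  for (i in seq_along(pos)) {
    substr(s, pos[i], ends[i]) <- seqs[i]
  }
  structure(list(residues = s, source_name = cs$source_name),
            class = "clean_sequence")
}

## Deterministically mutate bases so that no string in `sites` occurs in the
## sequence, except where an occurrence lies wholly inside a protected span.
## Used to build backgrounds with a fully controlled site landscape.
scrub_sites <- function(seq, sites, keep = NULL, max_iter = 50L) {
  cs <- as_clean_sequence(seq)
  s <- cs$residues
  keep_from <- keep_to <- integer(0)
  if (!is.null(keep) && nrow(keep)) {
    keep_from <- as.integer(keep$position)
    keep_to <- keep_from + nchar(keep$sequence) - 1L
  }
  protected <- function(p) {
    any(keep_from <= p & p <= keep_to)
  }
  wlen <- max(nchar(sites))
  ## unprotected site occurrences whose span covers position q: zero after a
  ## mutation at q means the mutation destroyed its target occurrence and
  ## created nothing new, so the global occurrence count strictly decreases.
  occ_at <- function(str, q) {
    a <- max(1L, q - wlen + 1L); b <- min(nchar(str), q + wlen - 1L)
    win <- substr(str, a, b)
    sum(vapply(sites, function(w) {
      pp <- find_sites(win, w) + a - 1L
      pp <- pp[pp <= q & q <= pp + nchar(w) - 1L]
      sum(!vapply(pp, function(p) {
        all(vapply(p:(p + nchar(w) - 1L), protected, NA))
      }, NA))
    }, 0L))
  }
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (site in sites) {
      for (p in find_sites(s, site)) {
        if (substr(s, p, p + nchar(site) - 1L) != site) next  # already fixed
        span <- p:(p + nchar(site) - 1L)
        free <- span[!vapply(span, protected, NA)]
        if (!length(free)) next  # wholly inside a protected span: planted
        ## first (position, base) whose mutation removes this occurrence
        ## without creating any other; fall back to the best available
        best <- NULL
        for (q in free) {
          for (base in setdiff(DNA_BASES, substr(s, q, q))) {
            trial <- s
            substr(trial, q, q) <- base
            sc <- occ_at(trial, q)
            if (is.null(best) || sc < best$sc) best <- list(q = q, base = base, sc = sc)
            if (sc == 0L) break
          }
          if (!is.null(best) && best$sc == 0L) break
        }
        substr(s, best$q, best$q) <- best$base
        dirty <- TRUE
      }
    }
    if (!dirty) {
      return(structure(list(residues = s, source_name = cs$source_name),
                       class = "clean_sequence"))
    }
  }
  stop("scrub_sites did not converge", call. = FALSE)
}

## Junction rotation for plannable targets: disjoint enzyme pairs drawn
## from different compatibility classes, plus palindromic options, so that
## strict sequential assembly is satisfiable by construction.
PLANNABLE_JUNCTIONS <- list(
  c("NcoI", "PciI"), c("BamHI", "BclI"), c("XhoI", "SalI"),
  c("XbaI", "NheI"), c("EcoRI", "EcoRI"), c("AvrII", "SpeI"),
  c("SacI", "SacI"))

#' Build a synthetic target with a fully controlled junction landscape
#'
#' Generates a random background, removes every fixture recognition site
#' and hybrid sequence from it, then plants one junction site roughly every
#' `module_len` bp, rotating through enzyme pairs from distinct
#' compatibility classes (with palindromic EcoRI/SacI junctions in the
#' rotation). The result is plannable under strict sequential constraints,
#' with the planted junctions as the only candidates.
#'
#' @param seed integer seed (controls background and position jitter).
#' @param n_modules number of modules (2..8).
#' @param module_len nominal module length in bp.
#' @param enzymes an `enzyme_set` (the bundled fixture set by default).
#' @param jitter maximum +/- displacement of each junction from its nominal
#'   position.
#' @return list with `seq` (a `clean_sequence`), `region` `(1, L)`, and
#'   `junctions` (data frame: `position`, `sequence`, `kind`, `left`,
#'   `right`).
#' @export
plannable_target <- function(seed, n_modules = 4L, module_len = 750L,
                             enzymes = read_enzyme_table(mac_enzyme_file()),
                             jitter = 40L) {
  n_modules <- as.integer(n_modules)
  if (n_modules < 2L || n_modules > length(PLANNABLE_JUNCTIONS) + 1L) {
    stop(sprintf("n_modules must be in 2..%d", length(PLANNABLE_JUNCTIONS) + 1L),
         call. = FALSE)
  }
  L <- n_modules * as.integer(module_len)
  base <- random_sequence(L, seed)
  offsets <- with_seed(seed + 1L, sample(-jitter:jitter, n_modules - 1L, replace = TRUE))
  specs <- PLANNABLE_JUNCTIONS[seq_len(n_modules - 1L)]
  plants <- do.call(rbind, lapply(seq_along(specs), function(k) {
    pair <- specs[[k]]
    l <- enzyme_lookup(enzymes, pair[1]); r <- enzyme_lookup(enzymes, pair[2])
    if (l$site == r$site) {
      kind <- "palindromic"; sq <- l$site
    } else {
      kind <- "hybrid"; sq <- hybrid_site(l, r)$sequence
    }
    data.frame(position = k * as.integer(module_len) + offsets[k], sequence = sq,
               kind = kind, left = l$name, right = r$name,
               stringsAsFactors = FALSE)
  }))
  all_words <- unique(c(enzymes$site, hybrid_table(enzymes)$sequence))
  planted <- plant_sites(base, plants)
  clean <- scrub_sites(planted, all_words, keep = plants)
  list(seq = clean, region = c(1L, L),
       junctions = plants[, c("position", "sequence", "kind", "left", "right")])
}

#' Build a surrogate target for a printed module table
#'
#' The worked-example tables print coordinates and flanking enzymes but not
#' the genomic residues. This builder lays the reconstructed junction
#' 6-mers onto a seeded random background at the printed relative offsets,
#' so that junction geometry and classification can be exercised without
#' the reference sequence. The background is random: tests against a
#' surrogate may assert junction geometry, never residue content.
#'
#' @param modules module table (see [chef1_module_tables()]).
#' @param enzymes an `enzyme_set`.
#' @param seed integer seed for the background.
#' @return list with `seq` (a `clean_sequence` starting at the table's
#'   first coordinate), `offset` (the table coordinate of position 1), and
#'   `junctions` (from [junctions_from_module_table()], plus a
#'   `rel_position` column).
#' @export
surrogate_target <- function(modules, enzymes, seed = 1L) {
  js <- junctions_from_module_table(modules, enzymes)
  offset <- min(modules$start)
  L <- max(modules$end) - offset + 1L
  ## junction site start in table coordinates: at a palindromic junction the
  ## next module starts on the site; at a hybrid junction, one base into it.
  pos_abs <- ifelse(js$kind == "palindromic",
                    modules$start[js$index + 1L],
                    modules$start[js$index + 1L] - 1L)
  js$rel_position <- as.integer(pos_abs - offset + 1L)
  plants <- data.frame(position = js$rel_position, sequence = js$sequence,
                       stringsAsFactors = FALSE)
  seq <- plant_sites(random_sequence(L, seed), plants)
  seq$source_name <- sprintf("surrogate_%d_%d", offset, max(modules$end))
  list(seq = seq, offset = offset, junctions = js)
}
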