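# In-silico restriction digestion and cohesive-end ligation, used to verify
# that an assembly plan reconstructs the target byte-for-byte and that every
# digestion step cuts only where intended.
#
# Fragment model: a linear duplex is represented by its top strand plus
# (sequence, polarity) annotations for the single-stranded extensions at
# each end. With symmetric type II cuts the top strand always splits at a
# single point per site -- after `cut_offset` bases for a 5' enzyme, after
# `6 - cut_offset` for its mirrored bottom cut never entering the top
# coordinate -- so concatenating fragment top strands in order reconstructs
# the input exactly, and a ligation joins two top strands with the shared
# overhang counted once.

overhang_end <- function(seq = "", polarity = "blunt") {
  list(seq = seq, polarity = polarity)
}

#' Construct a simulation fragment
#'
#' @param top top-strand sequence (A/C/G/T), including any single-stranded
#'   extension bases.
#' @param left_overhang,right_overhang lists with elements `seq` and
#'   `polarity` (`"five_prime"`, `"three_prime"` or `"blunt"`); defaults
#'   are blunt/undefined ends.
#' @return a `sim_fragment`.
#' @export
sim_fragment <- function(top, left_overhang = overhang_end(),
                         right_overhang = overhang_end()) {
  check_dna(top, "fragment top strand")
  structure(list(top = top, left_overhang = left_overhang,
                 right_overhang = right_overhang),
            class = "sim_fragment")
}

as_sim_fragment <- function(x) {
  if (inherits(x, "sim_fragment")) return(x)
  if (inherits(x, "clean_sequence")) return(sim_fragment(x$residues))
  if (is.character(x) && length(x) == 1L) return(sim_fragment(toupper(x)))
  stop("cannot interpret input as a fragment", call. = FALSE)
}

#' Digest a linear fragment with one enzyme
#'
#' Cuts at every recognition-site occurrence on the top strand (the sites
#' in scope are palindromic, so a top-strand scan covers both strands) and
#' returns the fragments left to right. Each internal boundary carries the
#' enzyme's overhang sequence and polarity on both facing ends; the outer
#' ends of the input are preserved. Zero sites returns the input unchanged
#' as a single fragment.
#'
#' @param x a `sim_fragment`, `clean_sequence`, or plain ACGT string.
#' @param enzyme enzyme name or one-row enzyme record.
#' @param enzymes an `enzyme_set`, required when a name is given.
#' @return list of `sim_fragment`s.
#' @examples
#' es <- read_enzyme_table(mac_enzyme_file())
#' frags <- digest("AAGGATCCTT", "BamHI", es)
#' vapply(frags, `[[`, "", "top")  # "AAG" "GATCCTT"
#' @export
digest <- function(x, enzyme, enzymes = NULL) {
  frag <- as_sim_fragment(x)
  e <- as_enzyme(enzyme, enzymes)
  pos <- find_sites(frag$top, e$site)
  cuts <- sort(unique(pos + e$cut_offset - 1L))
  cuts <- cuts[cuts >= 1L & cuts < nchar(frag$top)]
  if (!length(cuts)) return(list(frag))
  bounds <- c(0L, cuts, nchar(frag$top))
  lapply(seq_len(length(bounds) - 1L), function(i) {
    sim_fragment(
      substr(frag$top, bounds[i] + 1L, bounds[i + 1L]),
      left_overhang = if (i == 1L) frag$left_overhang else
        overhang_end(e$overhang, e$end_type),
      right_overhang = if (i == length(bounds) - 1L) frag$right_overhang else
        overhang_end(e$overhang, e$end_type))
  })
}

#' Ligate two fragments by their facing cohesive ends
#'
#' Requires the left fragment's right end and the right fragment's left
#' end to carry the same non-empty overhang sequence with the same
#' polarity. The joined top strand is the plain concatenation (the shared
#' overhang is present on exactly one side's top strand, by the fragment
#' model); the join position is recorded in `attr(, "join")`.
#'
#' @param left,right `sim_fragment`s.
#' @return the joined `sim_fragment`.
#' @export
ligate <- function(left, right) {
  stopifnot(inherits(left, "sim_fragment"), inherits(right, "sim_fragment"))
  a <- left$right_overhang; b <- right$left_overhang
  if (a$polarity == "blunt" || b$polarity == "blunt" ||
      !nzchar(a$seq) || !nzchar(b$seq)) {
    stop("blunt-end ligation is not supported", call. = FALSE)
  }
  if (a$seq != b$seq || a$polarity != b$polarity) {
    stop(sprintf("incompatible ends: %s (%s) vs %s (%s)",
                 a$seq, a$polarity, b$seq, b$polarity), call. = FALSE)
  }
  out <- sim_fragment(paste0(left$top, right$top),
                      left_overhang = left$left_overhang,
                      right_overhang = right$right_overhang)
  attr(out, "join") <- nchar(left$top)
  out
}

#' @export
print.sim_fragment <- function(x, ...) {
  fmt <- function(o) if (o$polarity == "blunt") "blunt" else
    sprintf("%s %s", o$seq, o$polarity)
  n <- nchar(x$top)
  cat(sprintf("<sim_fragment> %d nt [%s | %s]\n", n,
              fmt(x$left_overhang), fmt(x$right_overhang)))
  cat(substr(x$top, 1, min(n, 60)), if (n > 60) "...\n" else "\n", sep = "")
  invisible(x)
}

empty_violations <- function() {
  data.frame(step = integer(0), enzyme = character(0), position = integer(0),
             context = character(0), stringsAsFactors = FALSE)
}

violation_row <- function(step, enzyme, position, context) {
  data.frame(step = as.integer(step), enzyme = enzyme,
             position = if (is.na(position)) NA_integer_ else as.integer(position),
             context = context, stringsAsFactors = FALSE)
}

new_safety_report <- function(violations) {
  violations <- violations[order(violations$step, violations$enzyme,
                                 violations$position, method = "radix",
                                 na.last = TRUE), , drop = FALSE]
  rownames(violations) <- NULL
  structure(list(violations = violations, clean = nrow(violations) == 0L),
            class = "safety_report")
}

#' @export
print.safety_report <- function(x, ...) {
  if (x$clean) {
    cat("<safety_report> clean: every digestion cuts only its intended junction\n")
  } else {
    cat(sprintf("<safety_report> %d violation(s):\n", nrow(x$violations)))
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

module_amplicon <- function(plan, target, k) {
  m <- plan$modules
  paste0(m$five_added[k], substr(target, m$start[k], m$end[k]), m$three_added[k])
}

#' Simulate the sequential restriction-ligation assembly of a plan
#'
#' Builds each module's amplicon (genomic span plus primer-added terminal
#' bases), then assembles left to right: at step k the growing assembly's
#' right end is digested with junction k's left enzyme, the incoming
#' module's left end with its right enzyme, and the compatible ends are
#' ligated. Every off-target cut observed during a digestion is recorded;
#' the intended product is followed regardless, so one run reports all
#' issues. A digestion that fails to cut at its intended junction site is
#' an error.
#'
#' @param plan an `assembly_plan` from [plan_partition()] (or constructed
#'   to the same contract).
#' @param target the target `clean_sequence` (or raw text) the plan was
#'   made for.
#' @param enzymes an `enzyme_set`; defaults to the one stored in the plan.
#' @return list (class `assembly_sim_result`) with `assembled` (the
#'   region-aligned product, which equals `substr(target, region[1],
#'   region[2])` iff the assembly is seamless), `assembled_full` (including
#'   primer-added terminal bases), and `report` (a `safety_report`).
#' @export
simulate_assembly <- function(plan, target, enzymes = plan$enzymes) {
  stopifnot(inherits(plan, "assembly_plan"))
  s <- as_clean_sequence(target)$residues
  m <- plan$modules
  js <- plan$junctions
  if (plan$region[2] > nchar(s)) {
    stop("target does not cover the plan region", call. = FALSE)
  }
  pad5 <- nchar(m$five_added[1])
  asm <- sim_fragment(module_amplicon(plan, s, 1L))
  viol <- empty_violations()

  for (k in seq_len(nrow(js))) {
    L <- enzyme_lookup(enzymes, js$left_enzyme[k])
    R <- enzyme_lookup(enzymes, js$right_enzyme[k])
    ## -- cut the growing assembly's right end with the left enzyme
    j_asm <- js$position[k] - m$start[1] + 1L + pad5
    posL <- find_sites(asm$top, L$site)
    if (!(j_asm %in% posL)) {
      stop(sprintf("junction %d: no %s site at the expected assembly position",
                   k, L$name), call. = FALSE)
    }
    for (p in setdiff(posL, j_asm)) {
      if (p <= pad5) {
        viol <- rbind(viol, violation_row(k, L$name, NA, "terminal-5 primer site"))
      } else {
        viol <- rbind(viol, violation_row(k, L$name, p - pad5 + m$start[1] - 1L,
                                          sprintf("assembled modules 1..%d", k)))
      }
    }
    cut <- j_asm + L$cut_offset - 1L
    asm <- sim_fragment(substr(asm$top, 1L, cut),
                        left_overhang = asm$left_overhang,
                        right_overhang = overhang_end(L$overhang, L$end_type))
    ## -- cut the incoming module's left end with the right enzyme
    amp <- module_amplicon(plan, s, k + 1L)
    padk <- nchar(m$five_added[k + 1L])
    core_len <- m$end[k + 1L] - m$start[k + 1L] + 1L
    posR <- find_sites(amp, R$site)
    if (!(1L %in% posR)) {
      stop(sprintf("junction %d: no %s site at the start of module %d",
                   k, R$name, k + 1L), call. = FALSE)
    }
    for (p in setdiff(posR, 1L)) {
      if (p > padk + core_len) {
        viol <- rbind(viol, violation_row(k, R$name, NA, "terminal-3 primer site"))
      } else {
        viol <- rbind(viol, violation_row(k, R$name, p - padk + m$start[k + 1L] - 1L,
                                          sprintf("module %d", k + 1L)))
      }
    }
    incoming <- sim_fragment(substr(amp, R$cut_offset + 1L, nchar(amp)),
                             left_overhang = overhang_end(R$overhang, R$end_type))
    asm <- ligate(asm, incoming)
  }

  full <- asm$top
  pad3 <- nchar(m$three_added[nrow(m)])
  core <- substr(full, pad5 + 1L, nchar(full) - pad3)
  structure(list(assembled = core, assembled_full = full,
                 report = new_safety_report(viol)),
            class = "assembly_sim_result")
}

#' Static safety analysis of an assembly plan
#'
#' Re-derives, without simulating any cut or ligation, the off-target
#' digestion report of [simulate_assembly()]. In strict mode it scans, for
#' each junction, the same text the sequential assembly digests -- the
#' assembled prefix (5'-terminal primer site plus modules 1..k plus the
#' module's completing outer base) for the left enzyme, and the incoming
#' module's full amplicon for the right enzyme -- so its report equals the
#' dynamic one. Lenient mode checks only genomic occurrences inside the
#' two adjacent modules, exempting the junction 6-mers at the module
#' termini, and leaves wider enzyme reuse unreported. Both modes also
#' verify (defensively) that no formed hybrid junction 6-mer matches an
#' enzyme in the loaded set -- it cannot, while all loaded sites are
#' palindromic.
#'
#' @inheritParams simulate_assembly
#' @param strict defaults to the plan's `strict_sequential` configuration;
#'   strict mode matches the sequential simulation exactly.
#' @return a `safety_report`.
#' @export
assembly_safety_check <- function(plan, target, enzymes = plan$enzymes,
                                  strict = plan$config$strict_sequential) {
  stopifnot(inherits(plan, "assembly_plan"))
  s <- as_clean_sequence(target)$residues
  m <- plan$modules
  js <- plan$junctions
  viol <- empty_violations()
  pad5 <- nchar(m$five_added[1])

  for (k in seq_len(nrow(js))) {
    L <- enzyme_lookup(enzymes, js$left_enzyme[k])
    R <- enzyme_lookup(enzymes, js$right_enzyme[k])
    j <- js$position[k]
    pal_k <- js$kind[k] == "palindromic"

    if (strict) {
      ## left enzyme against the assembled prefix, as the simulation sees it
      prefix <- paste0(m$five_added[1], substr(s, m$start[1], m$end[k]),
                       m$three_added[k])
      j_asm <- j - m$start[1] + 1L + pad5
      for (p in setdiff(find_sites(prefix, L$site), j_asm)) {
        viol <- rbind(viol, if (p <= pad5) {
          violation_row(k, L$name, NA, "terminal-5 primer site")
        } else {
          violation_row(k, L$name, p - pad5 + m$start[1] - 1L,
                        sprintf("assembled modules 1..%d", k))
        })
      }
      ## right enzyme against the incoming module's amplicon
      amp <- module_amplicon(plan, s, k + 1L)
      padk <- nchar(m$five_added[k + 1L])
      core_len <- m$end[k + 1L] - m$start[k + 1L] + 1L
      for (p in setdiff(find_sites(amp, R$site), 1L)) {
        viol <- rbind(viol, if (p > padk + core_len) {
          violation_row(k, R$name, NA, "terminal-3 primer site")
        } else {
          violation_row(k, R$name, p - padk + m$start[k + 1L] - 1L,
                        sprintf("module %d", k + 1L))
        })
      }
    } else {
      intended_L <- if (pal_k) j else integer(0)
      prev_pos <- if (k > 1L) js$position[k - 1L] else integer(0)
      occ <- setdiff(occ_within(s, L$site, m$start[k], m$end[k]),
                     c(intended_L, prev_pos))
      for (p in occ) {
        viol <- rbind(viol, violation_row(k, L$name, p, sprintf("module %d", k)))
      }
      occ_r <- setdiff(occ_within(s, R$site, m$start[k + 1L], m$end[k + 1L]),
                       if (pal_k) j else integer(0))
      for (p in occ_r) {
        viol <- rbind(viol, violation_row(k, R$name, p, sprintf("module %d", k + 1L)))
      }
    }

    if (!pal_k) {
      inert_breakers <- enzymes$name[enzymes$site == js$sequence[k] |
                                       enzymes$site == revcomp(js$sequence[k])]
      for (nm in inert_breakers) {
        viol <- rbind(viol, violation_row(k, nm, j, "formed junction not inert"))
      }
    }
  }
  new_safety_report(viol)
}
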