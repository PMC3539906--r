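# File I/O and high-level entry points tying the modules together. These
# functions back the exec/macplan command-line script; results go to files
# and standard output, log chatter to standard error.

resolve_enzymes <- function(enzymes) {
  if (inherits(enzymes, "enzyme_set")) return(enzymes)
  if (is.character(enzymes) && length(enzymes) == 1L) {
    return(read_enzyme_table(enzymes))
  }
  stop("`enzymes` must be an enzyme_set or a table path", call. = FALSE)
}

resolve_sequence <- function(input) {
  if (inherits(input, "clean_sequence")) return(input)
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    return(read_sequence(input))
  }
  clean_sequence(input)
}

log_msg <- function(...) message(sprintf(...))

#' Format site hits as a human-readable report
#'
#' One line per hit: position, matched 6-mer, enzymes involved.
#' Palindromic restriction sites (recognised by one enzyme) are marked with
#' a trailing asterisk; hybrid sites are unmarked.
#'
#' @param hits a `site_hits` data frame from [scan_sites()].
#' @param source_name optional target name for the header.
#' @return character vector of report lines.
#' @export
format_site_report <- function(hits, source_name = NULL) {
  header <- c(sprintf("# site map%s",
                      if (!is.null(source_name)) paste0(": ", source_name) else ""),
              sprintf("# %d site(s); palindromic sites marked *", nrow(hits)))
  if (!nrow(hits)) return(c(header, "# no sites found"))
  body <- sprintf("%d\t%s\t%s%s", hits$position, hits$sequence, hits$enzymes,
                  ifelse(hits$kind == "palindromic", "\t*", ""))
  c(header, body)
}

#' Map palindromic and hybrid sites and write the results
#'
#' Scans the input, writes a delimited site table (`<prefix>_sites.tsv`:
#' position, sequence, kind, enzymes) and a text report
#' (`<prefix>_report.txt`) in which palindromic sites carry a trailing
#' asterisk, and returns the hits invisibly.
#'
#' @param input sequence file path, raw text, or a `clean_sequence`.
#' @param enzymes an `enzyme_set` or enzyme-table path.
#' @param out_dir output directory (created if needed).
#' @param prefix output file prefix.
#' @return the `site_hits` data frame, invisibly.
#' @export
run_map <- function(input, enzymes = mac_enzyme_file(), out_dir = ".",
                    prefix = "map") {
  es <- resolve_enzymes(enzymes)
  seq <- resolve_sequence(input)
  hits <- scan_sites(seq, es)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- file.path(out_dir, paste0(prefix, "_sites.tsv"))
  utils::write.table(as.data.frame(hits), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rpt <- file.path(out_dir, paste0(prefix, "_report.txt"))
  writeLines(format_site_report(hits, seq$source_name), rpt)
  if (!nrow(hits)) log_msg("no sites found in %d bp input", nchar(seq$residues))
  log_msg("wrote %s and %s (%d hits)", tsv, rpt, nrow(hits))
  invisible(hits)
}

#' Plan a module partition and write plan, amplicons and safety report
#'
#' Writes the plan table (`<prefix>_plan.tsv`, worked-example-style
#' columns, terminal enzymes parenthesised), a per-module amplicon FASTA
#' (`<prefix>_modules.fasta`, primer-added bases in lowercase) and the
#' safety report (`<prefix>_safety.txt`); returns the plan.
#'
#' @inheritParams run_map
#' @param region integer pair `(start, end)` on the target.
#' @param config a [planner_config()].
#' @return the `assembly_plan`, invisibly.
#' @export
run_plan <- function(input, region, enzymes = mac_enzyme_file(),
                     config = planner_config(), out_dir = ".",
                     prefix = "mac") {
  es <- resolve_enzymes(enzymes)
  seq <- resolve_sequence(input)
  plan <- plan_partition(seq, region, config, es)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tsv <- file.path(out_dir, paste0(prefix, "_plan.tsv"))
  utils::write.table(plan_table(plan), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fa <- file.path(out_dir, paste0(prefix, "_modules.fasta"))
  m <- plan$modules
  lines <- unlist(lapply(seq_len(nrow(m)), function(k) {
    amp <- paste0(tolower(m$five_added[k]),
                  substr(seq$residues, m$start[k], m$end[k]),
                  tolower(m$three_added[k]))
    c(sprintf(">module_%d %d-%d 5'=%s 3'=%s", k, m$start[k], m$end[k],
              ifelse(is.na(m$five_re[k]), ".", m$five_re[k]),
              ifelse(is.na(m$three_re[k]), ".", m$three_re[k])),
      amp)
  }))
  writeLines(lines, fa)
  sf <- file.path(out_dir, paste0(prefix, "_safety.txt"))
  if (plan$safety$clean) {
    writeLines("no violations", sf)
  } else {
    v <- plan$safety$violations
    writeLines(c("step\tenzyme\tposition\tcontext",
                 sprintf("%d\t%s\t%s\t%s", v$step, v$enzyme,
                         ifelse(is.na(v$position), ".", v$position), v$context)),
               sf)
  }
  log_msg("wrote %s, %s and %s (%d modules, %d junctions)", tsv, fa, sf,
          nrow(m), nrow(plan$junctions))
  invisible(plan)
}

#' Re-read a written plan table
#'
#' Round-trip companion to [run_plan()]: parses the delimited plan table
#' back into a module data frame with parenthesis markers preserved, from
#' which [junctions_from_module_table()] reconstructs the junctions.
#'
#' @param path path to a `*_plan.tsv` file.
#' @return data frame with columns `module`, `start`, `end`, `length`,
#'   `five_re`, `three_re`.
#' @export
read_plan_table <- function(path) {
  read_module_table(path)
}

#' Print site-occurrence statistics for a set of lengths
#'
#' @param lengths fragment lengths in bp.
#' @param out optional file path; omit to print to standard output.
#' @return the statistics data frame, invisibly.
#' @export
run_stats <- function(lengths, out = NULL) {
  tab <- site_stats_table(lengths)
  txt <- c("L\tp_no_site\tp_single\tp_multi",
           sprintf("%d\t%.4f\t%.4f\t%.4f", as.integer(tab$L), tab$p_no_site,
                   tab$p_single, tab$p_multi))
  if (is.null(out)) writeLines(txt) else writeLines(txt, out)
  invisible(tab)
}

#' Simulate an existing plan against a target and write the verdict
#'
#' @inheritParams run_map
#' @param plan an `assembly_plan`.
#' @return the simulation result, invisibly.
#' @export
run_simulate <- function(plan, input, out_dir = ".", prefix = "sim") {
  seq <- resolve_sequence(input)
  res <- simulate_assembly(plan, seq)
  target <- substr(seq$residues, plan$region[1], plan$region[2])
  seamless <- identical(res$assembled, target)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out <- file.path(out_dir, paste0(prefix, "_result.txt"))
  writeLines(c(sprintf("seamless\t%s", seamless),
               sprintf("violations\t%d", nrow(res$report$violations))), out)
  log_msg("assembly %s; %d violation(s); wrote %s",
          if (seamless) "is seamless" else "DIFFERS from target",
          nrow(res$report$violations), out)
  invisible(res)
}

#' Write synthetic FASTA fixtures
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param L random-sequence length in bp.
#' @param n_modules if `> 0`, additionally writes a plannable synthetic
#'   target with that many modules (see [plannable_target()]).
#' @return character vector of written paths, invisibly.
#' @export
run_fixtures <- function(out_dir = ".", seed = 1L, L = 3000L, n_modules = 0L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  rs <- random_sequence(L, seed)
  p <- file.path(out_dir, sprintf("random_L%d_seed%d.fasta", as.integer(L),
                                  as.integer(seed)))
  writeLines(c(paste0(">", rs$source_name), rs$residues), p)
  paths <- c(paths, p)
  if (n_modules > 0L) {
    pt <- plannable_target(seed, n_modules = n_modules)
    p2 <- file.path(out_dir, sprintf("plannable_%dmod_seed%d.fasta",
                                     as.integer(n_modules), as.integer(seed)))
    writeLines(c(paste0(">", pt$seq$source_name %||%
                          sprintf("plannable_seed%d", as.integer(seed))),
                 pt$seq$residues), p2)
    paths <- c(paths, p2)
  }
  log_msg("wrote %s", paste(paths, collapse = ", "))
  invisible(paths)
}
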