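# Enzyme table loading, validation and geometry derivation.
#
# Scope: type II restriction endonucleases with a non-ambiguous palindromic
# hexanucleotide recognition site. Enzymes producing 4-base 5' overhangs are
# eligible for hybrid-site generation; 3'-overhang and blunt cutters are
# retained for mapping and may serve at palindromic junctions (3' only).

ENZYME_COLUMNS <- c("name", "site", "cohesive_end", "end_type", "dam", "dcm")

normalize_end_type <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("5", "5'", "5p", "five_prime", "five-prime", "5prime")] <- "five_prime"
  out[x %in% c("3", "3'", "3p", "three_prime", "three-prime", "3prime")] <- "three_prime"
  out[x %in% c("blunt", "b", "0")] <- "blunt"
  bad <- !is.na(x) & nzchar(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("unrecognised end_type value(s): %s",
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' Derive cohesive-end geometry from a recognition site and cut offset
#'
#' Type II enzymes with palindromic sites cut symmetrically: if the top
#' strand is cut after `cut_offset` bases, the bottom strand is cut at the
#' mirrored position, duplicating the central segment between the two cuts
#' as a single-stranded extension. An offset left of centre leaves a 5'
#' overhang, right of centre a 3' overhang, and a centred cut is blunt.
#'
#' @param site recognition site, a 6-mer over A/C/G/T.
#' @param cut_offset integer 0..6, bases before the top-strand cut.
#' @return list with elements `overhang` (character, possibly empty) and
#'   `end_type` (`"five_prime"`, `"three_prime"` or `"blunt"`).
#' @examples
#' derive_overhang("CCATGG", 1)  # CATG, five_prime (NcoI)
#' derive_overhang("GAGCTC", 5)  # AGCT, three_prime (SacI)
#' derive_overhang("CACGTG", 3)  # blunt
#' @export
derive_overhang <- function(site, cut_offset) {
  site <- toupper(site)
  check_dna(site, "recognition site")
  if (nchar(site) != 6L) {
    stop("recognition site must be a hexanucleotide", call. = FALSE)
  }
  if (!is.numeric(cut_offset) || length(cut_offset) != 1L ||
      is.na(cut_offset) || cut_offset != round(cut_offset) ||
      cut_offset < 0 || cut_offset > 6) {
    stop("`cut_offset` must be an integer in 0..6", call. = FALSE)
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 3L) {
    list(overhang = substr(site, cut_offset + 1L, 6L - cut_offset),
         end_type = "five_prime")
  } else if (cut_offset > 3L) {
    list(overhang = substr(site, 7L - cut_offset, cut_offset),
         end_type = "three_prime")
  } else {
    list(overhang = "", end_type = "blunt")
  }
}

#' Dam/Dcm methylation-context flags for a recognition site
#'
#' Advisory heuristic: a site containing the Dam context `GATC`, or a Dcm
#' context `CCAGG`/`CCTGG`, may be blocked by E. coli methylation and is
#' inconvenient for cloning. Flanking-sequence-dependent sensitivity is not
#' modelled; explicit `dam`/`dcm` columns in the enzyme table override
#' these context flags.
#'
#' @param site recognition site, a 6-mer over A/C/G/T.
#' @return named logical vector with elements `dam` and `dcm`.
#' @examples
#' methylation_flags("TGATCA")  # BclI: dam TRUE
#' @export
methylation_flags <- function(site) {
  site <- toupper(site)
  check_dna(site, "recognition site")
  if (nchar(site) != 6L) {
    stop("recognition site must be a hexanucleotide", call. = FALSE)
  }
  c(dam = grepl("GATC", site, fixed = TRUE),
    dcm = grepl("CCAGG", site, fixed = TRUE) || grepl("CCTGG", site, fixed = TRUE))
}

#' Parse and validate a restriction-enzyme table
#'
#' Validates each row, derives cut geometry from the site and end type,
#' checks the cohesive-end field against the derived overhang, and merges
#' isoschizomers (rows sharing site, cut offset and end type) into a single
#' record carrying the extra names as synonyms.
#'
#' Rows whose site is not a non-ambiguous palindromic hexanucleotide
#' (ambiguity codes, wrong length, non-palindromes) are skipped with a
#' warning rather than aborting the load; the skipped rows are recorded in
#' `attr(x, "skipped")`. A cohesive-end value inconsistent with the derived
#' geometry is an error naming the offending row.
#'
#' @param x data frame with columns `name`, `site`, `cohesive_end`
#'   (mandatory; case-insensitive values) and optional `end_type`, `dam`,
#'   `dcm`. An empty cohesive-end value defaults to the 5', 4-base,
#'   cut-offset-1 convention.
#' @return an `enzyme_set`: data frame with columns `name`, `site`,
#'   `cut_offset`, `end_type`, `overhang`, `dam_blocked`, `dcm_blocked`,
#'   `hybrid_eligible` and list-column `synonyms`.
#' @seealso [read_enzyme_table()], [enzyme_lookup()]
#' @export
parse_enzyme_table <- function(x) {
  if (!is.data.frame(x)) stop("`x` must be a data frame", call. = FALSE)
  nm <- tolower(gsub("[^A-Za-z0-9]+", "_", names(x)))
  nm[nm %in% c("enzyme", "enzyme_name")] <- "name"
  nm[nm %in% c("recognition_site", "sequence")] <- "site"
  nm[nm %in% c("overhang", "cohesive_end_sequence")] <- "cohesive_end"
  nm[nm %in% c("polarity")] <- "end_type"
  names(x) <- nm
  missing_cols <- setdiff(c("name", "site", "cohesive_end"), nm)
  if (length(missing_cols)) {
    stop(sprintf("enzyme table format error: missing mandatory column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }

  records <- list()
  skipped <- data.frame(row = integer(0), name = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  skip <- function(i, name, reason) {
    skipped[nrow(skipped) + 1L, ] <<- list(i, name, reason)
  }

  for (i in seq_len(nrow(x))) {
    name <- trimws(as.character(x$name[i]))
    site <- toupper(trimws(as.character(x$site[i])))
    if (!nzchar(name)) { skip(i, name, "missing enzyme name"); next }
    if (nchar(site) != 6L) { skip(i, name, "ambiguous/invalid site: not a hexamer"); next }
    if (grepl("[^ACGT]", site)) { skip(i, name, "ambiguous/invalid site"); next }
    if (site != revcomp(site)) { skip(i, name, "non-palindromic site"); next }

    end_type <- if ("end_type" %in% nm) normalize_end_type(x$end_type[i]) else NA_character_
    if (is.na(end_type)) end_type <- "five_prime"
    cut_offset <- switch(end_type, five_prime = 1L, three_prime = 5L, blunt = 3L)
    geom <- derive_overhang(site, cut_offset)

    coh <- toupper(trimws(as.character(x$cohesive_end[i])))
    if (is.na(coh)) coh <- ""
    if (nzchar(coh) && coh != geom$overhang) {
      stop(sprintf(
        "enzyme table row %d (%s): cohesive end '%s' inconsistent with '%s' derived from site %s",
        i, name, coh, geom$overhang, site), call. = FALSE)
    }

    ctx <- methylation_flags(site)
    dam <- if ("dam" %in% nm) parse_flag(x$dam[i]) else NA
    dcm <- if ("dcm" %in% nm) parse_flag(x$dcm[i]) else NA
    records[[length(records) + 1L]] <- list(
      name = name, site = site, cut_offset = cut_offset,
      end_type = end_type, overhang = geom$overhang,
      dam_blocked = if (is.na(dam)) unname(ctx["dam"]) else dam,
      dcm_blocked = if (is.na(dcm)) unname(ctx["dcm"]) else dcm,
      hybrid_eligible = end_type == "five_prime" && nchar(geom$overhang) == 4L
    )
  }

  ## merge isoschizomers: identical (site, cut_offset, end_type)
  keys <- vapply(records, function(r) paste(r$site, r$cut_offset, r$end_type), "")
  keep <- !duplicated(keys)
  merged <- records[keep]
  synonyms <- lapply(merged, function(r) character(0))
  for (j in which(duplicated(keys))) {
    k <- match(keys[j], keys[keep])
    synonyms[[k]] <- c(synonyms[[k]], records[[j]]$name)
  }

  out <- data.frame(
    name = vapply(merged, `[[`, "", "name"),
    site = vapply(merged, `[[`, "", "site"),
    cut_offset = vapply(merged, `[[`, 0L, "cut_offset"),
    end_type = vapply(merged, `[[`, "", "end_type"),
    overhang = vapply(merged, `[[`, "", "overhang"),
    dam_blocked = vapply(merged, `[[`, NA, "dam_blocked"),
    dcm_blocked = vapply(merged, `[[`, NA, "dcm_blocked"),
    hybrid_eligible = vapply(merged, `[[`, NA, "hybrid_eligible"),
    stringsAsFactors = FALSE
  )
  out$synonyms <- synonyms
  class(out) <- c("enzyme_set", "data.frame")
  attr(out, "skipped") <- skipped
  if (nrow(skipped)) {
    warning(sprintf("skipped %d enzyme row(s): %s", nrow(skipped),
                    paste(sprintf("row %d (%s): %s", skipped$row,
                                  skipped$name, skipped$reason),
                          collapse = "; ")), call. = FALSE)
  }
  out
}

#' Read a delimited enzyme table from disk
#'
#' @param path path to a TSV (or CSV, by extension) file with a header row
#'   naming at least `name`, `site` and `cohesive_end`.
#' @return an `enzyme_set`; see [parse_enzyme_table()].
#' @examples
#' es <- read_enzyme_table(mac_enzyme_file())
#' @export
read_enzyme_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("enzyme table not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  parse_enzyme_table(utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                                       comment.char = "#"))
}

#' Serialise an enzyme set back to a delimited table
#'
#' Synonyms are written as separate rows sharing the canonical record's
#' geometry, so that re-parsing the file reproduces the same merged set.
#'
#' @param es an `enzyme_set`.
#' @param path output file path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_enzyme_table <- function(es, path) {
  stopifnot(inherits(es, "enzyme_set"))
  rows <- do.call(rbind, lapply(seq_len(nrow(es)), function(i) {
    nms <- c(es$name[i], es$synonyms[[i]])
    data.frame(name = nms, site = es$site[i], cohesive_end = es$overhang[i],
               end_type = es$end_type[i],
               dam = es$dam_blocked[i], dcm = es$dcm_blocked[i],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up an enzyme by canonical name or synonym
#'
#' @param es an `enzyme_set`.
#' @param name enzyme name (case-insensitive; isoschizomer synonyms
#'   resolve to the canonical record).
#' @return the matching one-row subset of `es`.
#' @examples
#' es <- read_enzyme_table(mac_enzyme_file())
#' enzyme_lookup(es, "AhlI")$name  # "SpeI"
#' @export
enzyme_lookup <- function(es, name) {
  stopifnot(inherits(es, "enzyme_set"))
  if (inherits(name, "enzyme_set")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  target <- tolower(trimws(name))
  hit <- which(vapply(seq_len(nrow(es)), function(i) {
    target %in% tolower(c(es$name[i], es$synonyms[[i]]))
  }, NA))
  if (length(hit) != 1L) {
    stop(sprintf("unknown enzyme '%s' (known: %s)", name,
                 paste(es$name, collapse = ", ")), call. = FALSE)
  }
  es[hit, , drop = FALSE]
}

## Resolve `enzyme` (name or one-row enzyme_set) to a one-row record.
as_enzyme <- function(enzyme, enzymes = NULL) {
  if (is.character(enzyme)) {
    if (is.null(enzymes)) stop("an enzyme_set is required to resolve enzyme names", call. = FALSE)
    return(enzyme_lookup(enzymes, enzyme))
  }
  if (is.data.frame(enzyme) && nrow(enzyme) == 1L) return(enzyme)
  stop("`enzyme` must be an enzyme name or a one-row enzyme record", call. = FALSE)
}

#' Path to the bundled enzyme fixture table
#'
#' Twelve common hexamer-cutting enzymes (XhoI, XbaI, BamHI, SalI, EcoRI,
#' NheI, BclI, SpeI, SacI, AvrII, NcoI, PciI) plus the isoschizomer rows
#' AhlI, Psp124BI, Ksp22I and AspA2I, which merge into their prototypes on
#' parsing.
#'
#' @return file path of the installed TSV fixture.
#' @export
mac_enzyme_file <- function() {
  system.file("extdata", "enzymes.tsv", package = "macplan", mustWork = TRUE)
}

#' @export
print.enzyme_set <- function(x, ...) {
  cat(sprintf("<enzyme_set> %d enzymes (%d hybrid-eligible)\n",
              nrow(x), sum(x$hybrid_eligible)))
  df <- as.data.frame(x)
  df$synonyms <- vapply(x$synonyms, paste, "", collapse = ",")
  print(df, row.names = FALSE)
  sk <- attr(x, "skipped")
  if (!is.null(sk) && nrow(sk)) cat(sprintf("(%d row(s) skipped at parse time)\n", nrow(sk)))
  invisible(x)
}
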