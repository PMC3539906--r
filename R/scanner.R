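# Input cleaning and site scanning.

#' Clean raw sequence text into validated residues
#'
#' Accepts a single-record FASTA or pasted plain text. A leading `>` header
#' line is captured as the source name; digits, whitespace and
#' record-numbering punctuation are stripped from the body (so
#' GenBank-style numbered listings paste cleanly); letters are uppercased
#' and validated as A/C/G/T only. Ambiguity codes are rejected, not treated
#' as wildcards.
#'
#' @param text character scalar or vector of lines.
#' @param source_name optional name overriding any FASTA header.
#' @return a `clean_sequence`: list with `residues` (uppercase ACGT string)
#'   and `source_name` (or `NULL`).
#' @examples
#' clean_sequence("60 acgtACGT\n120 ggcc")$residues  # "ACGTACGTGGCC"
#' @export
clean_sequence <- function(text, source_name = NULL) {
  if (inherits(text, "clean_sequence")) return(text)
  stopifnot(is.character(text))
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 0L]
  header_idx <- grep("^\\s*>", lines)
  if (length(header_idx) > 1L) {
    stop("multi-record FASTA input: run one record at a time", call. = FALSE)
  }
  if (length(header_idx) == 1L) {
    if (header_idx != 1L) {
      stop("multi-record FASTA input: run one record at a time", call. = FALSE)
    }
    if (is.null(source_name)) {
      source_name <- trimws(sub("^\\s*>", "", lines[1L]))
    }
    lines <- lines[-1L]
  }
  body <- paste(lines, collapse = "")
  body <- gsub("[0-9[:space:]]", "", body)
  body <- toupper(body)
  bad <- regexpr("[^ACGT]", body)
  if (bad > 0L) {
    stop(sprintf("invalid symbol '%s' at offset %d after cleaning",
                 substr(body, bad, bad), bad), call. = FALSE)
  }
  structure(list(residues = body, source_name = source_name),
            class = "clean_sequence")
}

#' Read and clean a sequence file (FASTA or plain text)
#'
#' @param path file path.
#' @return a `clean_sequence`; see [clean_sequence()].
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop(sprintf("sequence file not found: %s", path), call. = FALSE)
  clean_sequence(readLines(path, warn = FALSE))
}

as_clean_sequence <- function(x) {
  if (inherits(x, "clean_sequence")) x else clean_sequence(x)
}

#' @export
print.clean_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("<clean_sequence> %s%d bp\n",
              if (!is.null(x$source_name)) paste0(x$source_name, ", ") else "", n))
  if (n) cat(substr(x$residues, 1, min(n, 60)),
             if (n > 60) "...\n" else "\n", sep = "")
  invisible(x)
}

empty_hits <- function() {
  out <- data.frame(position = integer(0), sequence = character(0),
                    kind = character(0), enzymes = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("site_hits", "data.frame")
  out
}

#' Scan a sequence for palindromic and hybrid site occurrences
#'
#' Reports every (overlapping) occurrence of every enzyme recognition site
#' and of every non-palindromic hybrid sequence, sorted by position then
#' sequence. Palindromic sites need only forward-strand matching; for
#' hybrids, scanning both orientations of each ordered pair covers both
#' genomic strands, since the sequence of (A, B) is the reverse complement
#' of the sequence of (B, A).
#'
#' One row is emitted per (position, sequence): a palindromic hit names
#' every enzyme recognising the site once (isoschizomers having been merged
#' at parse time), and a hybrid hit lists all ordered `left+right` pairs
#' producing that sequence, comma-separated.
#'
#' @param seq a `clean_sequence`, or text acceptable to [clean_sequence()].
#' @param enzymes an `enzyme_set`.
#' @param hybrids hybrid pair table from [hybrid_table()] (default); pass a
#'   subset to restrict the hybrid search.
#' @return data frame (class `site_hits`) with columns `position` (1-based
#'   start), `sequence`, `kind` (`"palindromic"`/`"hybrid"`), `enzymes`.
#' @examples
#' es <- read_enzyme_table(mac_enzyme_file())
#' scan_sites("AACCATGTTT", es)  # one hybrid hit at 3: NcoI+PciI
#' @export
scan_sites <- function(seq, enzymes, hybrids = hybrid_table(enzymes)) {
  stopifnot(inherits(enzymes, "enzyme_set"))
  s <- as_clean_sequence(seq)$residues
  if (nchar(s) < 6L) return(empty_hits())

  rows <- list()
  for (site in unique(enzymes$site)) {
    pos <- find_sites(s, site)
    if (!length(pos)) next
    label <- paste(sort(enzymes$name[enzymes$site == site]), collapse = ",")
    rows[[length(rows) + 1L]] <- data.frame(
      position = pos, sequence = site, kind = "palindromic",
      enzymes = label, stringsAsFactors = FALSE)
  }
  hy <- hybrids[!hybrids$is_palindromic, , drop = FALSE]
  for (sq in unique(hy$sequence)) {
    pos <- find_sites(s, sq)
    if (!length(pos)) next
    sub <- hy[hy$sequence == sq, , drop = FALSE]
    label <- paste(paste0(sub$left, "+", sub$right), collapse = ",")
    rows[[length(rows) + 1L]] <- data.frame(
      position = pos, sequence = sq, kind = "hybrid",
      enzymes = label, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_hits())
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_hits", "data.frame")
  out
}
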