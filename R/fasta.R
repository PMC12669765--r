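#' @title FASTA input/output with the sequence+structure dialect
#' @description Standard multi-record FASTA plus the FASTA-like dialect in
#'   which a record carries a dot-bracket structure line after its sequence
#'   line(s). Structure lines are auto-detected (lines consisting solely of
#'   structure characters `.()[]{}<>&`); such a record feeds
#'   [from_structure()] directly. Letter-coded pseudoknot layers cannot be
#'   auto-detected in this dialect and belong in target files instead.
#' @name fasta
NULL

.STRUCT_LINE_RE <- "^[][(){}<>&.]+$"

#' Load FASTA records
#'
#' @param path FASTA file
#' @return list of records `list(name, sequence, structure)` (`structure`
#'   `NULL` for plain records); empty list (with a warning) for an empty file
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  starts <- grep("^>", lines)
  if (length(starts) == 0L || starts[1] != 1L) {
    stop("malformed FASTA at line 1: expected '>' record header")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  records <- list()
  for (k in seq_along(starts)) {
    name <- sub("^>\\s*", "", lines[starts[k]])
    body <- lines[(starts[k] + 1L):ends[k]]
    if (starts[k] == ends[k]) {
      stop("malformed FASTA at line ", starts[k], ": record '", name,
           "' has no sequence")
    }
    is_struct <- grepl(.STRUCT_LINE_RE, body)
    structure_line <- NULL
    if (any(is_struct)) {
      structure_line <- paste(body[is_struct], collapse = "")
      body <- body[!is_struct]
    }
    records[[k]] <- list(name = name,
                         sequence = toupper(paste(body, collapse = "")),
                         structure = structure_line)
  }
  records
}

#' Write FASTA records
#'
#' @param records list of `list(name, sequence, structure = NULL)`
#' @param path output file
#' @export
write_fasta <- function(records, path) {
  out <- unlist(lapply(records, function(r) {
    c(paste0(">", r$name), r$sequence, r$structure)
  }))
  writeLines(out %||% character(0), path)
  invisible(path)
}
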