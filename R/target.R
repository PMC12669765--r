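#' @title Design targets: sequence constraints + layered dot-bracket
#' @description The hand-off from structure design to sequence design: an
#'   IUPAC constraint string (strand breaks marked `&`) and a dot-bracket
#'   string of equal length, with pseudoknot layers on their own bracket
#'   alphabets. The 3-line target file (name, constraints, structure) is the
#'   interchange format consumed by inverse-folding engines.
#' @name target
NULL

#' Create a target specification
#'
#' @param constraints IUPAC constraint string, `&` between strands
#' @param structure layered dot-bracket of equal length
#' @param name design name
#' @param wobble optional two-column matrix/data.frame of pair positions
#'   (1-based nucleotide indices) where G-U is permitted
#' @return object of class `target_spec`
#' @export
target_spec <- function(constraints, structure, name = "design", wobble = NULL) {
  if (nchar(constraints) != nchar(structure)) {
    stop("constraints and structure lengths differ (",
         nchar(constraints), " vs ", nchar(structure), ")")
  }
  cc <- chars(constraints); sc <- chars(structure)
  if (!identical(which(cc == "&"), which(sc == "&"))) {
    stop("strand breaks '&' in constraints and structure do not align")
  }
  bad <- setdiff(unique(cc), c(iupac_letters(), "&", "T"))
  if (length(bad) > 0L) {
    stop("invalid constraint code(s): ", paste(bad, collapse = " "))
  }
  parsed <- parse_dotbracket(structure)
  letters <- cc[cc != "&"]
  letters[letters == "T"] <- "U"
  p <- parsed$pairs
  wob <- rep(FALSE, nrow(p))
  if (!is.null(wobble) && nrow(p) > 0L) {
    wobkey <- paste(pmin(wobble[, 1], wobble[, 2]),
                    pmax(wobble[, 1], wobble[, 2]))
    wob <- paste(p$i, p$j) %in% wobkey
  }
  if (nrow(p) > 0L) {
    for (r in seq_len(nrow(p))) {
      if (!iupac_can_pair(letters[p$i[r]], letters[p$j[r]], wobble = wob[r])) {
        # the 3-line file format carries no wobble channel: when no explicit
        # wobble map was given, pairs that are G-U-satisfiable are accepted
        # and flagged rather than rejected
        if (is.null(wobble) &&
            iupac_can_pair(letters[p$i[r]], letters[p$j[r]], wobble = TRUE)) {
          wob[r] <- TRUE
          next
        }
        stop("paired constraints ", letters[p$i[r]], "-", letters[p$j[r]],
             " at positions ", p$i[r], "-", p$j[r],
             " have no complementary base combination")
      }
    }
  }
  structure(list(name = name, constraints = toupper(constraints),
                 structure = structure, pairs = cbind(p, wobble = wob),
                 n = parsed$n, breaks = parsed$breaks),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat("<target_spec> ", x$name, ": ", x$n, " nt, ",
      nrow(x$pairs), " pairs (", sum(x$pairs$layer > 0L), " pseudoknot)\n",
      sep = "")
  cat("  ", x$constraints, "\n  ", x$structure, "\n", sep = "")
  invisible(x)
}

#' Derive the design target from an origami
#'
#' Strand constraints are joined 5' to 3' with `&`; layer-0 pairs are written
#' `()`, pseudoknot layers get `[]`, `{}`, `<>`, then letter pairs, assigned
#' greedily in order of first occurrence.
#'
#' @param x an `origami` or `origami_blueprint`
#' @param name design name
#' @return a [target_spec()]
#' @export
to_target <- function(x, name = "design") {
  bp <- if (inherits(x, "origami_blueprint")) x else assemble(x)
  lens <- nchar(bp$strands)
  breaks <- if (length(lens) > 1L) cumsum(lens)[-length(lens)] else integer(0)
  db <- format_dotbracket(bp$n_nt, bp$pairs, breaks)
  wob <- if (nrow(bp$pairs) > 0L) {
    as.matrix(bp$pairs[bp$pairs$wobble, c("i", "j"), drop = FALSE])
  }
  target_spec(paste(bp$strands, collapse = "&"), db, name = name, wobble = wob)
}

#' Write a target file
#'
#' 3-line plain-text format: name, IUPAC constraints (with `&` strand
#' breaks), dot-bracket structure of equal length.
#'
#' @param spec a [target_spec()]
#' @param path output file
#' @export
write_target <- function(spec, path) {
  stopifnot(inherits(spec, "target_spec"))
  writeLines(c(spec$name, spec$constraints, spec$structure), path)
  invisible(path)
}

#' Read a target file
#'
#' @param path 3-line target file
#' @return a [target_spec()]
#' @export
read_target <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) != 3L) {
    stop("malformed target file '", path, "': expected 3 lines (name, ",
         "constraints, structure), found ", length(ln))
  }
  if (nchar(ln[2]) != nchar(ln[3])) {
    stop("malformed target file '", path,
         "': line 3 (structure) length ", nchar(ln[3]),
         " does not match line 2 (constraints) length ", nchar(ln[2]))
  }
  target_spec(ln[2], ln[3], name = ln[1])
}
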