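#' @title IUPAC nucleotide code utilities
#' @description Internal machinery for the 15-letter IUPAC ambiguity alphabet
#'   used throughout the blueprint and sequence-design layers. Sequences are
#'   RNA by convention (U, not T) except in the DNA conversion/primer layer,
#'   where T is used; both letters are accepted on input and treated as the
#'   same base class.
#' @name iupac
#' @keywords internal
NULL

# base classes for each IUPAC code (RNA letters; T is an alias of U)
.IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

.IUPAC_COMPLEMENT <- c(
  A = "U", C = "G", G = "C", U = "A", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# canonical letter for each sorted base set
.IUPAC_FROM_SET <- local({
  keys <- vapply(.IUPAC[setdiff(names(.IUPAC), "T")],
                 function(b) paste(sort(b), collapse = ""), character(1))
  stats::setNames(names(keys), keys)
})

iupac_letters <- function() setdiff(names(.IUPAC), "T")

is_iupac <- function(chars) chars %in% names(.IUPAC)

#' Expand an IUPAC code to its base class
#' @param x single character
#' @return character vector of concrete bases (A/C/G/U)
#' @keywords internal
iupac_bases <- function(x) {
  b <- .IUPAC[[x]]
  if (is.null(b)) stop("not an IUPAC nucleotide code: '", x, "'", call. = FALSE)
  b
}

# letter representing a set of concrete bases
iupac_letter <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  out <- .IUPAC_FROM_SET[[key]]
  if (is.null(out)) stop("no IUPAC code for base set {", key, "}", call. = FALSE)
  out
}

# intersection of two codes, "" if empty
iupac_intersect <- function(x, y) {
  common <- intersect(iupac_bases(x), iupac_bases(y))
  if (length(common) == 0L) return("")
  iupac_letter(common)
}

#' Reverse complement of an IUPAC string (RNA convention)
#' @param seq character scalar
#' @return character scalar
#' @export
#' @examples
#' reverse_complement("GGAACC")
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L) stop("seq must be a single string")
  if (nchar(seq) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- .IUPAC_COMPLEMENT[ch]
  if (anyNA(comp)) {
    stop("invalid nucleotide code(s): ",
         paste(unique(ch[is.na(comp)]), collapse = ", "))
  }
  paste(rev(unname(comp)), collapse = "")
}

# allowed concrete base pairs (x, y unordered)
.WC_PAIRS <- list(c("A", "U"), c("U", "A"), c("C", "G"), c("G", "C"))
.WOBBLE_PAIRS <- list(c("G", "U"), c("U", "G"))

#' Can two IUPAC codes form a base pair?
#'
#' TRUE when the two base classes contain at least one allowed complementary
#' combination (Watson-Crick always; G-U additionally when `wobble` is TRUE).
#' @param x,y single IUPAC characters
#' @param wobble logical, permit G-U
#' @keywords internal
iupac_can_pair <- function(x, y, wobble = FALSE) {
  bx <- iupac_bases(x); by <- iupac_bases(y)
  rules <- if (wobble) c(.WC_PAIRS, .WOBBLE_PAIRS) else .WC_PAIRS
  for (p in rules) if (p[1] %in% bx && p[2] %in% by) return(TRUE)
  FALSE
}

# concrete letters x may take such that some partner letter in class(y) pairs with it
iupac_pairing_options <- function(x, y, wobble = FALSE) {
  bx <- iupac_bases(x); by <- iupac_bases(y)
  rules <- if (wobble) c(.WC_PAIRS, .WOBBLE_PAIRS) else .WC_PAIRS
  keep <- vapply(bx, function(a) {
    any(vapply(rules, function(p) p[1] == a && p[2] %in% by, logical(1)))
  }, logical(1))
  bx[keep]
}

# partner letters in class(y) that pair with the concrete base a
iupac_partners_of <- function(a, y, wobble = FALSE) {
  by <- iupac_bases(y)
  rules <- if (wobble) c(.WC_PAIRS, .WOBBLE_PAIRS) else .WC_PAIRS
  unique(unlist(lapply(rules, function(p) if (p[1] == a && p[2] %in% by) p[2])))
}

# split a string into single characters
chars <- function(x) if (nchar(x) == 0L) character(0) else strsplit(x, "", fixed = TRUE)[[1]]

#' Convert RNA to DNA lettering and back
#' @param seq character scalar
#' @return character scalar
#' @keywords internal
rna_to_dna_letters <- function(seq) chartr("Uu", "Tt", seq)

#' @keywords internal
dna_to_rna_letters <- function(seq) chartr("Tt", "Uu", seq)
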