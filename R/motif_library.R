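#' @title Parametric motif constructors
#' @description The small set of structural motifs from which an RNA origami
#'   raster is assembled: stems, tetraloops, dovetail crossovers and
#'   180-degree kissing loops, plus an extensible aptamer catalog and the
#'   dot-bracket Structure Converter. All constructors are pure: the same
#'   parameters always give identical motifs.
#' @name motif_library
NULL

# A cap: one strand entering on the top line travelling east, U-turning and
# leaving on the bottom line travelling west. Used for tetraloops, terminal
# kissing-loop hairpins and aptamer caps. n >= 2 nucleotides.
cap_motif <- function(seq, name, kind, pairs = NULL, meta = list()) {
  letters <- chars(seq)
  n <- length(letters)
  if (n < 2L) stop("cap motif needs at least 2 nucleotides")
  k <- ceiling(n / 2)           # nucleotides on the top line
  m <- n - k
  glyphs <- c(letters[seq_len(k)], "\u256e", "\u256f",
              letters[(k + 1L):n], rep("\u2500", k - m))
  motif(name, kind, list(strand(glyphs, c(0L, 0L), "right")),
        pairs = pairs, meta = meta)
}

#' Double-helical stem
#'
#' Two antiparallel strands of `length_bp` base pairs: the top strand reads
#' west to east, the complement east to west. A fraction of the pairs can be
#' flagged wobble-permitted, allowing G-U there during sequence design.
#'
#' @param length_bp number of base pairs (>= 1)
#' @param sequence_constraint optional IUPAC constraint for the top strand
#'   (length `length_bp`); the bottom strand is its reverse complement
#' @param wobble_fraction fraction of pairs flagged wobble-permitted;
#'   `round(wobble_fraction * length_bp)` evenly spread positions are flagged
#' @return an `origami_motif` of kind `"stem"`
#' @export
#' @examples
#' stem(5)
#' stem(4, "GGCC")
stem <- function(length_bp, sequence_constraint = NULL, wobble_fraction = 0) {
  n <- as.integer(length_bp)
  if (is.na(n) || n < 1L) stop("length_bp must be a positive integer")
  if (wobble_fraction < 0 || wobble_fraction > 1) {
    stop("wobble_fraction must be in [0, 1]")
  }
  top <- if (is.null(sequence_constraint) || nchar(sequence_constraint) == 0L) {
    strrep("N", n)
  } else {
    if (nchar(sequence_constraint) != n) {
      stop("sequence_constraint must have length 0 or ", n)
    }
    toupper(sequence_constraint)
  }
  bottom <- reverse_complement(top)
  k <- round(wobble_fraction * n)
  wob <- rep(FALSE, n)
  if (k > 0L) {
    at <- unique(round(seq(1L, n, length.out = k)))
    if (length(at) < k) at <- seq_len(k)
    wob[at] <- TRUE
  }
  pairs <- data.frame(i = seq_len(n), j = 2L * n + 1L - seq_len(n),
                      layer = 0L, wobble = wob)
  motif(paste0("stem-", n), "stem",
        list(strand(top, c(0L, 0L), "right"),
             strand(bottom, c(1L, n - 1L), "left")),
        pairs = pairs,
        meta = list(length_bp = n, wobble_fraction = wobble_fraction))
}

.TETRALOOPS <- c(UUCG = "UUCG", GAAA = "GAAA", GCAA = "GCAA",
                 GAGA = "GAGA", GUGA = "GUGA", GUAA = "GUAA")

#' Tetraloop cap
#'
#' A 4-nucleotide hairpin loop closing one helix end. The packaged set
#' contains the UUCG loop (default) and common GNRA-class loops.
#'
#' @param kind loop sequence name, one of UUCG, GAAA, GCAA, GAGA, GUGA, GUAA
#' @return an `origami_motif` of kind `"tetraloop"`
#' @export
tetraloop <- function(kind = "UUCG") {
  if (!kind %in% names(.TETRALOOPS)) {
    stop("unknown tetraloop '", kind, "'; packaged loops: ",
         paste(names(.TETRALOOPS), collapse = ", "))
  }
  cap_motif(.TETRALOOPS[[kind]], paste0("tetraloop-", kind), "tetraloop",
            meta = list(loop = kind))
}

#' Dovetail crossover
#'
#' A double-crossover junction connecting two vertically adjacent helix rows.
#' The motif is minimal: one crossover base pair on each side of an
#' inter-crossover seam stem of `abs(offset_bp)` base pairs shared between the
#' two pass-through strands; flanking duplexes are supplied by neighbouring
#' stem motifs. The blueprint layout is identical for both offset signs; the
#' sign selects the handedness of the inter-helix dihedral used by the 3D
#' builder and is carried in the motif metadata.
#'
#' @param offset_bp signed seam length in base pairs
#' @param segment_lengths lengths of the helix segments flanking the
#'   crossovers; the seam may not be longer than either
#' @return an `origami_motif` of kind `"dovetail"` spanning two helix rows
#' @export
dovetail <- function(offset_bp, segment_lengths = c(abs(offset_bp), abs(offset_bp))) {
  d <- abs(as.integer(offset_bp))
  if (length(segment_lengths) != 2L || any(segment_lengths < 0L)) {
    stop("segment_lengths must be two non-negative integers")
  }
  if (d > min(segment_lengths) && d > 0L) {
    stop("dovetail offset ", offset_bp, " too large for segments (",
         paste(segment_lengths, collapse = ", "), ")")
  }
  W <- max(d, 2L) + 4L
  pad <- max(0L, 2L - d)     # spacer path glyphs when the seam is short
  mid <- if (d > 0L) strrep("N", d) else ""
  t_glyphs <- c("\u2500", "N", chars(mid), rep("\u2500", pad), "N", "\u2500")
  b_glyphs <- t_glyphs
  Tstr <- strand(t_glyphs, c(0L, 0L), "right")
  Bstr <- strand(b_glyphs, c(3L, W - 1L), "left")
  Cstr <- strand(c("\u2500", "N", "\u256f", "\u256e", "N", "\u2500"),
                 c(2L, 0L), "right")
  Astr <- strand(c("\u2500", "N", "\u256d", "\u2570", "N", "\u2500"),
                 c(1L, W - 1L), "left")
  # local nucleotide indices: T: 1..d+2, C: d+3, d+4, A: d+5, d+6, B: d+7..2d+8
  pairs <- rbind(
    data.frame(i = 1L, j = d + 4L),              # T west - C upper
    data.frame(i = d + 3L, j = 2L * d + 8L),     # C lower - B west
    data.frame(i = d + 2L, j = d + 5L),          # T east - A upper
    data.frame(i = d + 6L, j = d + 7L),          # A lower - B east
    if (d > 0L) data.frame(i = 1L + seq_len(d), j = 2L * d + 8L - seq_len(d))
  )
  pairs$layer <- 0L; pairs$wobble <- FALSE
  motif(paste0("dovetail", ifelse(offset_bp >= 0, "+", ""), offset_bp),
        "dovetail",
        list(Tstr, Cstr, Astr, Bstr), pairs = pairs,
        meta = list(offset_bp = as.integer(offset_bp),
                    segment_lengths = as.integer(segment_lengths),
                    rows_spanned = 2L))
}

#' Kissing-loop specification
#'
#' @param loop1,loop2 7-nucleotide IUPAC loop constraints, 5' to 3'. The first
#'   position of each loop is an unpaired spacer; positions 2-7 form the
#'   6-base-pair kissing duplex and must be reverse-complement compatible
#'   between the two loops. When `loop2` is omitted it is derived as the
#'   kissing complement of `loop1`.
#' @param topology `"intra_strand_180"` (two facing hairpins inside one
#'   design), `"dimeric"` (same layout, loops annotated as an intermolecular
#'   dimer interface) or `"branched"` (a single terminal hairpin whose kissing
#'   partner is external, e.g. on the next tile of a filament)
#' @param energy_kcal nominal loop-loop binding energy, annotation only
#' @return a `kissing_loop_spec` list
#' @export
kissing_loop_spec <- function(loop1 = "ANNNNNN", loop2 = NULL,
                              topology = c("intra_strand_180", "dimeric",
                                           "branched"),
                              energy_kcal = NA_real_) {
  topology <- match.arg(topology)
  loop1 <- toupper(loop1)
  if (nchar(loop1) != 7L) stop("kissing loops are 7 nucleotides")
  if (is.null(loop2)) {
    loop2 <- paste0(substr(loop1, 1L, 1L), reverse_complement(substr(loop1, 2L, 7L)))
  }
  loop2 <- toupper(loop2)
  if (nchar(loop2) != 7L) stop("kissing loops are 7 nucleotides")
  c1 <- chars(loop1); c2 <- chars(loop2)
  for (k in 2:7) {
    if (!iupac_can_pair(c1[k], c2[9L - k])) {
      stop("kissing-loop cores are not reverse-complement compatible at loop1 position ", k)
    }
  }
  structure(list(loop1 = loop1, loop2 = loop2, topology = topology,
                 energy_kcal = energy_kcal),
            class = "kissing_loop_spec")
}

# single kissing hairpin as a cap; kiss pairs at the given pseudoknot layer
# are added by the caller when the partner is in the same motif
kl_hairpin <- function(loop, name) {
  cap_motif(loop, name, "kissing_loop")
}

#' 180-degree kissing loop
#'
#' Two hairpin loops meeting coaxially: the strand arriving from the west
#' U-turns in the left hairpin, the strand arriving from the east U-turns in
#' the right hairpin, and the loop cores pair with each other on pseudoknot
#' layer 1. The `"branched"` topology yields the single terminal hairpin
#' variant whose kissing partner lies outside the design.
#'
#' @param spec a [kissing_loop_spec()]
#' @return an `origami_motif` of kind `"kissing_loop"`
#' @export
kissing_loop_180 <- function(spec = kissing_loop_spec()) {
  if (!inherits(spec, "kissing_loop_spec")) spec <- do.call(kissing_loop_spec, spec)
  if (spec$topology == "branched") {
    m <- kl_hairpin(spec$loop1, "kl180-terminal")
    m$meta <- c(m$meta, list(kl = spec, external_partner = TRUE))
    return(m)
  }
  left <- kl_hairpin(spec$loop1, "kl-left")
  right <- transform_motif(kl_hairpin(spec$loop2, "kl-right"), "rotate_180")
  # place the right hairpin east of the left one
  lw <- motif_extents(left)["max_col"] + 1L
  rstrands <- lapply(right$strands, function(s) {
    s$start[2] <- s$start[2] + lw
    s
  })
  pairs <- data.frame(i = 2:7, j = 16L - (2:7), layer = 1L, wobble = FALSE)
  motif(paste0("kl180-", spec$topology), "kissing_loop",
        c(left$strands, rstrands), pairs = pairs,
        meta = list(kl = spec))
}

# packaged aptamer catalog: literature sequences with fold-predicted internal
# pairing (used as annotation; the aptamer is sequence-fixed either way)
.APTAMERS <- list(
  Broccoli = list(
    seq = "GAGACGGUCGGGUCCAGAUAUUCGUAUCUGUCGAGUAGAGUGUGGGCUC",
    db  = ".........(((((((..((((((.......)))))).....)))))))",
    source = "Filonov et al. 2014, J Am Chem Soc 136:16299 (fluorescence light-up aptamer, DFHBI-1T)"
  ),
  MS2_hairpin = list(
    seq = "ACAUGAGGAUUACCCAUGU",
    db  = "(((((.((....)))))))",
    source = "Peabody 1993, EMBO J 12:595 (MS2 coat-protein binding hairpin)"
  )
)

#' Aptamer catalog motif
#'
#' Returns a sequence-fixed cap motif from the packaged catalog. Internal
#' pairing is annotated from a thermodynamic fold prediction of the catalog
#' sequence; 3D poses are placeholder helical geometry.
#'
#' @param name catalog entry name
#' @return an `origami_motif` of kind `"aptamer"`
#' @export
#' @examples
#' aptamer("Broccoli")
aptamer <- function(name) {
  entry <- .APTAMERS[[name]]
  if (is.null(entry)) {
    stop("unknown aptamer '", name, "'; catalog: ",
         paste(names(.APTAMERS), collapse = ", "))
  }
  parsed <- parse_dotbracket(entry$db)
  pairs <- parsed$pairs
  if (nrow(pairs) > 0L) {
    letters <- chars(entry$seq)
    pairs$wobble <- !mapply(function(i, j) iupac_can_pair(letters[i], letters[j]),
                            pairs$i, pairs$j)
  }
  cap_motif(entry$seq, name, "aptamer", pairs = pairs,
            meta = list(source = entry$source, structure = entry$db))
}

#' Names of packaged aptamers
#' @export
aptamer_catalog <- function() names(.APTAMERS)

#' Custom motif from explicit strand specifications
#'
#' The custom-motif interface: every strand is given by its glyph string,
#' start position and start direction (optionally per-nucleotide 3D poses),
#' together with a local pair list. The result is a first-class motif usable
#' anywhere a library motif is.
#'
#' @param strands list of strand specifications: either [strand()] objects or
#'   lists with elements `glyphs`, `start`, `direction`, optional `poses`
#' @param pairs data.frame `i`, `j` (+ optional `layer`, `wobble`), local
#'   1-based nucleotide indices
#' @param name motif name
#' @param meta metadata list
#' @return an `origami_motif` of kind `"custom"`
#' @export
custom_motif <- function(strands, pairs = NULL, name = "custom", meta = list()) {
  strands <- lapply(strands, function(s) {
    if (inherits(s, "origami_strand")) s
    else strand(s$glyphs, s$start %||% c(0L, 0L), s$direction %||% "right",
                s$poses)
  })
  motif(name, "custom", strands, pairs = pairs, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Structure Converter: dot-bracket to motif
#'
#' Converts layered dot-bracket notation (and an optional sequence) into a
#' motif, one glyph line per strand. When no sequence is given, positions are
#' filled with `N` except 4-nucleotide layer-0 hairpin loops, which receive
#' the packaged default UUCG loop. Pseudoknot layers are preserved in the pair
#' map. For pseudoknot-free inputs the target derived from the motif
#' reproduces `(sequence, dot_bracket)` exactly.
#'
#' @param dot_bracket layered dot-bracket string, `&` for strand breaks
#' @param sequence optional IUPAC sequence, same length (with `&` at the same
#'   positions)
#' @return an `origami_motif` of kind `"custom"`
#' @export
#' @examples
#' from_structure("((..))", "GGAACC")
from_structure <- function(dot_bracket, sequence = NULL) {
  parsed <- parse_dotbracket(dot_bracket)
  n <- parsed$n
  if (n == 0L) stop("empty structure")
  if (!is.null(sequence)) {
    if (nchar(sequence) != nchar(dot_bracket)) {
      stop("sequence and structure lengths differ (",
           nchar(sequence), " vs ", nchar(dot_bracket), ")")
    }
    seq_ch <- chars(toupper(sequence))
    amp_s <- which(seq_ch == "&"); amp_d <- which(chars(dot_bracket) == "&")
    if (!identical(amp_s, amp_d)) {
      stop("strand breaks '&' in sequence and structure do not align")
    }
    letters <- seq_ch[seq_ch != "&"]
    letters[letters == "T"] <- "U"
  } else {
    letters <- rep("N", n)
    # default-fill 4-nt hairpin loops closed by a nested pair
    p0 <- parsed$pairs[parsed$pairs$layer == 0L, , drop = FALSE]
    if (nrow(p0) > 0L) {
      loop4 <- p0[p0$j - p0$i == 5L, , drop = FALSE]
      paired_any <- c(parsed$pairs$i, parsed$pairs$j)
      for (r in seq_len(nrow(loop4))) {
        span <- (loop4$i[r] + 1L):(loop4$j[r] - 1L)
        if (!any(span %in% paired_any)) letters[span] <- chars("UUCG")
      }
    }
  }
  pairs <- parsed$pairs
  if (nrow(pairs) > 0L) {
    pairs$wobble <- !mapply(function(i, j) iupac_can_pair(letters[i], letters[j]),
                            pairs$i, pairs$j)
    bad <- which(pairs$wobble &
                   !mapply(function(i, j) iupac_can_pair(letters[i], letters[j], TRUE),
                           pairs$i, pairs$j))
    if (length(bad) > 0L) {
      stop("pair between incompatible bases ", letters[pairs$i[bad[1]]], "-",
           letters[pairs$j[bad[1]]], " at positions ",
           pairs$i[bad[1]], "-", pairs$j[bad[1]])
    }
  }
  # strand boundaries from '&'
  bounds <- c(0L, parsed$breaks, n)
  strands <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    span <- (bounds[k] + 1L):bounds[k + 1L]
    strands[[k]] <- strand(letters[span], c(k - 1L, 0L), "right")
  }
  motif("from_structure", "custom", strands, pairs = pairs,
        meta = list(structure = dot_bracket))
}
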