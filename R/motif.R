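#' @title Motifs: the unit of origami assembly
#' @description A motif is a named collection of strands on a small glyph
#'   grid together with a local base-pair map. Junctions -- the points where a
#'   strand enters or leaves the motif -- are derived from the strand walks:
#'   every strand start is a 5' junction and every strand end a 3' junction,
#'   with an attached travel direction. During assembly a 3' junction connects
#'   to the 5' junction of the glyph-adjacent cell in its travel direction.
#' @name motif
NULL

#' Create a motif
#'
#' @param name motif name
#' @param kind one of `"tetraloop"`, `"stem"`, `"dovetail"`, `"kissing_loop"`,
#'   `"aptamer"`, `"connector"`, `"custom"`
#' @param strands list of [strand()] objects
#' @param pairs data.frame with columns `i`, `j` (1-based local nucleotide
#'   indices, counted across strands in list order, 5' to 3'), `layer`
#'   (0 = nested secondary structure, >= 1 = pseudoknot layer) and `wobble`
#'   (logical: G-U permitted at this pair). Missing columns default to layer 0,
#'   no wobble.
#' @param meta named list of free-form metadata (source citation, PDB id,
#'   geometry parameters)
#' @return an object of class `origami_motif`
#' @export
motif <- function(name, kind = "custom", strands = list(), pairs = NULL,
                  meta = list()) {
  kinds <- c("tetraloop", "stem", "dovetail", "kissing_loop", "aptamer",
             "connector", "custom")
  if (!kind %in% kinds) {
    stop("kind must be one of ", paste(kinds, collapse = ", "))
  }
  if (is.null(pairs)) {
    pairs <- data.frame(i = integer(0), j = integer(0))
  }
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$layer)) pairs$layer <- rep(0L, nrow(pairs))
  if (is.null(pairs$wobble)) pairs$wobble <- rep(FALSE, nrow(pairs))
  # normalize i < j
  if (nrow(pairs) > 0L) {
    swap <- pairs$i > pairs$j
    tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
  }
  m <- structure(
    list(name = name, kind = kind, strands = strands,
         pairs = pairs[, c("i", "j", "layer", "wobble")], meta = meta),
    class = "origami_motif")
  validate_motif(m)
  m
}

#' Validate a motif
#'
#' Checks strand walks (alphabet, self-avoidance, collisions between strands),
#' the local pair map (involution, index range, non-crossing layer 0, IUPAC
#' pairing compatibility) and pose counts.
#'
#' @param m an `origami_motif`
#' @return the motif, invisibly; errors describe the violation
#' @export
validate_motif <- function(m) {
  walks <- lapply(m$strands, walk_strand)
  if (length(walks) > 0L) {
    cells <- do.call(rbind, lapply(walks, function(w) w[, c("row", "col")]))
    key <- paste(cells$row, cells$col)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop("motif '", m$name, "': strands collide at grid cell (",
           sub(" ", ",", d), ")")
    }
  }
  n_nt <- sum(vapply(m$strands, strand_nt, integer(1)))
  p <- m$pairs
  if (nrow(p) > 0L) {
    if (any(p$i < 1L | p$j > n_nt)) {
      stop("motif '", m$name, "': pair index outside 1..", n_nt)
    }
    if (any(p$i == p$j)) stop("motif '", m$name, "': base paired with itself")
    idx <- c(p$i, p$j)
    if (anyDuplicated(idx)) {
      stop("motif '", m$name, "': nucleotide in more than one pair")
    }
    # local index order is only meaningful for a single strand; pairs of
    # multi-strand motifs interleave globally and are checked at assembly
    if (length(m$strands) == 1L &&
        any_crossing(p[p$layer == 0L, , drop = FALSE])) {
      stop("motif '", m$name, "': crossing pairs in the nested layer")
    }
    seqs <- motif_constraints(m)
    for (r in seq_len(nrow(p))) {
      a <- seqs[p$i[r]]; b <- seqs[p$j[r]]
      if (!iupac_can_pair(a, b, wobble = p$wobble[r])) {
        stop("motif '", m$name, "': pair ", p$i[r], "-", p$j[r], " (", a,
             "-", b, ") has no complementary base combination")
      }
    }
  }
  invisible(m)
}

# concatenated per-nucleotide constraint letters, strands in order
motif_constraints <- function(m) {
  unlist(lapply(m$strands, function(s) s$glyphs[is_nucleotide_glyph(s$glyphs)]),
         use.names = FALSE)
}

#' Number of nucleotides in a motif
#' @param m an `origami_motif`
#' @export
motif_nt <- function(m) sum(vapply(m$strands, strand_nt, integer(1)))

#' Number of base pairs declared by a motif
#' @param m an `origami_motif`
#' @export
motif_pairs <- function(m) nrow(m$pairs)

# inclusive 0-based extents over all strand cells
motif_extents <- function(m) {
  walks <- lapply(m$strands, walk_strand)
  cells <- do.call(rbind, lapply(walks, function(w) w[, c("row", "col")]))
  c(max_row = max(cells$row), max_col = max(cells$col))
}

#' Flip or rotate a motif
#'
#' Mirrors the glyph paths, junction directions and any local 3D poses;
#' the pair map is unchanged (flipping relabels geometry, not pairing).
#' Needed to orient motifs on upper versus lower helix rows of a serpentine
#' design. `rotate_180` is the composition of the two flips.
#'
#' @param m an `origami_motif`
#' @param op `"flip_horizontal"`, `"flip_vertical"` or `"rotate_180"`
#' @return the transformed motif
#' @export
transform_motif <- function(m, op = c("flip_horizontal", "flip_vertical",
                                      "rotate_180")) {
  op <- match.arg(op)
  steps <- switch(op,
    flip_horizontal = "h",
    flip_vertical = "v",
    rotate_180 = c("h", "v"))
  out <- m
  for (ax in steps) {
    ext <- motif_extents(out)
    out$strands <- lapply(out$strands, function(s) {
      s2 <- flip_strand(s, ax, ext["max_row"], ext["max_col"])
      if (!is.null(s2$poses)) {
        # mirror the matching spatial coordinate of position and orientation
        # vectors (x tracks columns, y tracks rows)
        cidx <- if (ax == "h") c(1L, 4L, 7L) else c(2L, 5L, 8L)
        s2$poses[, cidx] <- -s2$poses[, cidx]
      }
      s2
    })
  }
  out
}

#' @export
print.origami_motif <- function(x, ...) {
  cat("<origami_motif> ", x$name, " [", x$kind, "]\n", sep = "")
  cat("  strands: ", length(x$strands),
      ", nucleotides: ", motif_nt(x),
      ", pairs: ", motif_pairs(x),
      if (any(x$pairs$layer > 0L)) " (incl. pseudoknot)" else "", "\n", sep = "")
  grid <- motif_glyph_grid(x)
  for (line in grid) cat("  ", line, "\n", sep = "")
  invisible(x)
}

# render a motif's glyphs on its own small grid
motif_glyph_grid <- function(m) {
  walks <- lapply(m$strands, walk_strand)
  cells <- do.call(rbind, lapply(walks, function(w) w[, c("row", "col", "glyph")]))
  if (is.null(cells) || nrow(cells) == 0L) return(character(0))
  nr <- max(cells$row) + 1L; nc <- max(cells$col) + 1L
  grid <- matrix(" ", nr, nc)
  grid[cbind(cells$row + 1L, cells$col + 1L)] <- cells$glyph
  apply(grid, 1L, paste, collapse = "")
}

#' Junctions of a motif
#'
#' One row per strand terminus: 5' junctions are strand starts (the direction
#' is the incoming travel direction expected from a neighbour), 3' junctions
#' are strand ends (the direction points to the neighbouring cell the strand
#' hands over to).
#'
#' @param m an `origami_motif`
#' @return data.frame with `strand`, `polarity` ("5p"/"3p"), `row`, `col`,
#'   `direction`
#' @export
motif_junctions <- function(m) {
  out <- lapply(seq_along(m$strands), function(k) {
    w <- walk_strand(m$strands[[k]])
    data.frame(
      strand = k,
      polarity = c("5p", "3p"),
      row = c(w$row[1], w$row[nrow(w)]),
      col = c(w$col[1], w$col[nrow(w)]),
      direction = c(w$dir_in[1], attr(w, "exit_dir")),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
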