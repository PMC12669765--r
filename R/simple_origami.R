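#' @title Simple origami generation and packaged demo designs
#' @description `make_simple_origami()` builds the canonical RNA origami
#'   raster: `n_helices` parallel helices capped with tetraloops, joined by
#'   one dovetail crossover per inter-helix junction in every helix segment,
#'   and segmented by columns of 180-degree kissing loops. One helix row per
#'   kissing-loop column bridges the gap with a plain stem so that the whole
#'   raster remains a single backbone cycle: the segment/crossover graph is a
#'   spanning tree ((n-1)(k+1) crossover merges over n(k+1) - k segment
#'   cycles), which is nicked once into a linear single strand.
#' @name simple_origami
NULL

#' Generate a rectangular multi-helix origami
#'
#' @param n_helices number of parallel helices (>= 2)
#' @param dovetails signed dovetail offsets, one per inter-helix junction
#'   (length `n_helices - 1`); the sign sets the handedness of the inter-helix
#'   dihedral. Alternating signs give a flat (corrugated) sheet.
#' @param kl_columns number of kissing-loop columns segmenting the helices
#' @param stem_length base pairs per stem slot (two slots per helix segment);
#'   edge helices receive compensating padding so all rows span equal widths
#' @param kl_loop 7-nt IUPAC loop constraint used for all kissing loops
#' @param bridge_rows 0-based helix row bridging each kissing-loop column with
#'   a plain stem (default: evenly spread)
#' @param bridge_length base pairs of each bridge stem (default 10, matching
#'   the kissing-loop glyph width)
#' @param insertions list of cap replacements, each
#'   `list(motif =, row =, side = "east"|"west")`; the motif (e.g. an aptamer
#'   cap) replaces the tetraloop cap of that row
#' @param terminal_kl 0-based rows whose end caps become terminal
#'   (externally kissing) 180-degree hairpins, e.g. for filament
#'   polymerisation; applied to both ends of the row
#' @param terminal_kl_loop loop for terminal hairpins (default palindromic,
#'   so any two tile ends can kiss)
#' @param extra_east_bp extra base pairs added to the east-most stem of the
#'   last helix; the free length knob used to meet an exact design size
#' @param tetraloop_kind cap loop (default UUCG)
#' @return an `origami`
#' @export
make_simple_origami <- function(n_helices,
                                dovetails = rep_len(c(-5L, 5L), n_helices - 1L),
                                kl_columns = 0L,
                                stem_length = 7L,
                                kl_loop = "ANNNNNN",
                                bridge_rows = NULL,
                                bridge_length = 10L,
                                insertions = list(),
                                terminal_kl = integer(0),
                                terminal_kl_loop = "AGGAUCC",
                                extra_east_bp = 0L,
                                tetraloop_kind = "UUCG") {
  n <- as.integer(n_helices)
  if (is.na(n) || n < 2L) stop("n_helices must be >= 2")
  k <- as.integer(kl_columns)
  dovetails <- as.integer(dovetails)
  if (length(dovetails) != n - 1L) {
    stop("dovetails must list one offset per inter-helix junction (",
         n - 1L, " needed)")
  }
  if (any(abs(dovetails) > stem_length)) {
    stop("dovetail length ", max(abs(dovetails)),
         " exceeds stem segment length ", stem_length)
  }
  if (is.null(bridge_rows)) {
    bridge_rows <- if (k > 0L) {
      as.integer(round((seq_len(k) - 0.5) * n / k - 0.5)) %% n
    } else integer(0)
  }
  if (k > 0L && length(bridge_rows) != k) {
    stop("bridge_rows must name one helix row per kissing-loop column")
  }
  dt_width <- function(d) max(abs(d), 2L) + 4L

  cap_for <- function(r, side) {
    ins <- Filter(function(x) x$row == r && x$side == side, insertions)
    base <- if (length(ins) == 1L) {
      ins[[1]]$motif
    } else if (r %in% terminal_kl) {
      kissing_loop_180(kissing_loop_spec(terminal_kl_loop,
                                         topology = "branched"))
    } else {
      tetraloop(tetraloop_kind)
    }
    if (side == "west") transform_motif(base, "rotate_180") else base
  }

  rows <- vector("list", n)
  for (r in seq_len(n) - 1L) {
    row <- list(cap_for(r, "west"))
    # padding for the junction this edge row does not have
    pad <- 0L
    if (r == 0L && n > 2L) pad <- dt_width(dovetails[2])
    if (r == n - 1L && n > 2L) pad <- dt_width(dovetails[n - 2L])
    pad_w <- pad %/% 2L; pad_e <- pad - pad_w
    for (s in 0:k) {
      east_extra <- if (r == n - 1L && s == k) as.integer(extra_east_bp) else 0L
      row <- c(row, list(stem(stem_length + pad_w)))
      if (r < n - 1L) {
        d <- dovetails[r + 1L]
        row <- c(row, list(dovetail(d, c(stem_length, stem_length))))
      }
      row <- c(row, list(stem(stem_length + pad_e + east_extra)))
      if (s < k) {
        row <- c(row, list(
          if (bridge_rows[s + 1L] == r) stem(bridge_length)
          else kissing_loop_180(kissing_loop_spec(kl_loop))))
      }
    }
    row <- c(row, list(cap_for(r, "east")))
    rows[[r + 1L]] <- row
  }
  origami(rows)
}

#' Two-layer filament tile demo
#'
#' An origami tile that polymerises into filaments: a corrugated base layer of
#' six parallel helices (alternating -5/+5 dovetails) plus a second layer of
#' two helices folded on top by short +/-2 dovetail junctions. The first base
#' helix carries palindromic terminal 180-degree kissing loops on both ends so
#' that tiles can kiss head-to-tail. Stem lengths are chosen to make the tile
#' clearly longer than it is wide.
#'
#' @param stem_length base pairs per stem slot (default 35)
#' @return an `origami`
#' @export
demo_filament_tile <- function(stem_length = 35L) {
  make_simple_origami(
    n_helices = 8L,
    dovetails = c(-5L, 5L, -5L, 5L, -5L, -2L, 2L),
    kl_columns = 0L,
    stem_length = stem_length,
    terminal_kl = 0L)
}

#' Rect-10H-3X demo: a large rectangular origami
#'
#' Ten parallel helices joined by alternating +/-5 dovetail crossovers in
#' every segment and segmented by three columns of 180-degree kissing loops
#' (one bridging row per column keeps the design single-stranded). A Broccoli
#' aptamer cap replaces the east tetraloop of helix 4. With 7-bp stem slots
#' and 13 extra east base pairs the design totals exactly 2501 nucleotides in
#' one strand.
#'
#' @return an `origami`
#' @export
demo_rect_10h_3x <- function() {
  make_simple_origami(
    n_helices = 10L,
    dovetails = rep_len(c(-5L, 5L), 9L),
    kl_columns = 3L,
    stem_length = 7L,
    insertions = list(list(motif = aptamer("Broccoli"), row = 4L,
                           side = "east")),
    extra_east_bp = 13L)
}

#' Y-shaped droplet motif demo
#'
#' A three-armed junction for RNA condensate formation, built with the
#' Structure Converter: three 10-bp arms, each capped by a palindromic
#' kissing loop (kissing partners are on other molecules, so the loops are
#' unpaired within the design), connected at the centre by runs of five
#' unpaired uracils, plus a Broccoli aptamer hairpin for visualisation.
#'
#' @return an `origami` containing the converted motif
#' @export
demo_droplet_y <- function() {
  arm_db <- paste0(strrep("(", 10), ".......", strrep(")", 10))
  arm_ct <- paste0(strrep("N", 10), "AGGAUCC", strrep("N", 10))
  link <- strrep("U", 5)
  broc <- .APTAMERS$Broccoli
  db <- paste0(arm_db, strrep(".", 5), arm_db, strrep(".", 5),
               arm_db, strrep(".", 5), broc$db)
  ct <- paste0(arm_ct, link, arm_ct, link, arm_ct, link, broc$seq)
  origami(list(list(from_structure(db, ct))))
}

.DEMOS <- c("filament_tile", "rect_10h_3x", "droplet_y_motif")

#' Build a packaged demo design
#'
#' @param name one of `"filament_tile"`, `"rect_10h_3x"`, `"droplet_y_motif"`
#' @return an `origami`
#' @export
demo_design <- function(name) {
  switch(name,
    filament_tile = demo_filament_tile(),
    rect_10h_3x = demo_rect_10h_3x(),
    droplet_y_motif = demo_droplet_y(),
    stop("unknown demo '", name, "'; available: ",
         paste(.DEMOS, collapse = ", ")))
}
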