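#' @title Strands on the blueprint grid
#' @description A strand is an ordered run of glyphs walked across the
#'   character grid from a start cell in a start direction. Nucleotide glyphs
#'   (IUPAC codes) occupy one cell and keep the current direction; path glyphs
#'   route the walk: `─` (west-east) and `│` (north-south) pass
#'   straight through, while the corner glyphs `╭` (south-east),
#'   `╮` (south-west), `╰` (north-east) and `╯` (north-west)
#'   turn it. Grid coordinates are 0-based with the origin at the top left;
#'   rows grow downwards.
#' @name strand
NULL

.DIR_DELTA <- list(
  right = c(0L, 1L), left = c(0L, -1L), up = c(-1L, 0L), down = c(1L, 0L)
)
.DIRECTIONS <- names(.DIR_DELTA)

.OPPOSITE <- c(right = "left", left = "right", up = "down", down = "up")

# side of a cell from which a walk moving in `dir` entered
.ENTRY_SIDE <- c(right = "W", left = "E", up = "S", down = "N")
# direction of travel towards a side
.SIDE_DIR <- c(W = "left", E = "right", N = "up", S = "down")

# sides connected by each path glyph
.PATH_GLYPHS <- list(
  "\u2500" = c("W", "E"),  # ─
  "\u2502" = c("N", "S"),  # │
  "\u256d" = c("S", "E"),  # ╭
  "\u256e" = c("S", "W"),  # ╮
  "\u2570" = c("N", "E"),  # ╰
  "\u256f" = c("N", "W")   # ╯
)

is_nucleotide_glyph <- function(g) g %in% iupac_letters()
is_path_glyph <- function(g) g %in% names(.PATH_GLYPHS)

#' Create a strand
#'
#' @param glyphs character scalar or vector of single glyphs: IUPAC nucleotide
#'   codes and path glyphs
#' @param start integer pair `c(row, col)`, 0-based grid cell of the first glyph
#' @param direction one of `"right"`, `"left"`, `"up"`, `"down"`
#' @param poses optional matrix of per-nucleotide 3D poses (one row per
#'   nucleotide glyph, 9 columns: position, base vector, normal vector)
#' @return an object of class `origami_strand`
#' @export
strand <- function(glyphs, start = c(0L, 0L), direction = "right", poses = NULL) {
  if (length(glyphs) == 1L && nchar(glyphs) > 1L) glyphs <- chars(glyphs)
  glyphs <- toupper(glyphs)
  glyphs[glyphs == "T"] <- "U"
  bad <- glyphs[!(is_nucleotide_glyph(glyphs) | is_path_glyph(glyphs))]
  if (length(bad) > 0L) {
    stop("glyphs outside the blueprint alphabet: ",
         paste(unique(bad), collapse = " "))
  }
  if (!direction %in% .DIRECTIONS) {
    stop("direction must be one of ", paste(.DIRECTIONS, collapse = ", "))
  }
  start <- as.integer(start)
  if (length(start) != 2L || any(start < 0L)) {
    stop("start must be a non-negative c(row, col) grid index")
  }
  n_nt <- sum(is_nucleotide_glyph(glyphs))
  if (!is.null(poses)) {
    poses <- as.matrix(poses)
    if (nrow(poses) != n_nt || ncol(poses) != 9L) {
      stop("poses must have one 9-column row per nucleotide glyph (",
           n_nt, " expected, ", nrow(poses), " given)")
    }
  }
  out <- list(glyphs = glyphs, start = start, direction = direction, poses = poses)
  class(out) <- "origami_strand"
  out
}

#' Walk a strand across the grid
#'
#' Computes the cell and travel direction of every glyph and checks the walk
#' for self-intersection and negative coordinates.
#'
#' @param s an `origami_strand`
#' @return data.frame with columns `row`, `col`, `glyph`, `dir_in`, `dir_out`,
#'   `is_nt`; attribute `exit_dir` is the direction of travel after the final
#'   glyph.
#' @export
walk_strand <- function(s) {
  n <- length(s$glyphs)
  row <- col <- integer(n)
  dir_in <- dir_out <- character(n)
  pos <- s$start
  dir <- s$direction
  for (k in seq_len(n)) {
    if (any(pos < 0L)) {
      stop("strand walk leaves the grid at step ", k,
           " (row ", pos[1], ", col ", pos[2], ")")
    }
    row[k] <- pos[1]; col[k] <- pos[2]
    dir_in[k] <- dir
    g <- s$glyphs[k]
    if (is_path_glyph(g)) {
      sides <- .PATH_GLYPHS[[g]]
      from <- .ENTRY_SIDE[[dir]]
      if (!from %in% sides) {
        stop("path glyph '", g, "' at (", pos[1], ",", pos[2],
             ") cannot be entered moving ", dir)
      }
      dir <- .SIDE_DIR[[setdiff(sides, from)]]
    }
    dir_out[k] <- dir
    pos <- pos + .DIR_DELTA[[dir]]
  }
  key <- paste(row, col)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("strand path crosses itself at grid cell (",
         sub(" ", ",", d), ")")
  }
  out <- data.frame(row = row, col = col, glyph = s$glyphs,
                    dir_in = dir_in, dir_out = dir_out,
                    is_nt = is_nucleotide_glyph(s$glyphs),
                    stringsAsFactors = FALSE)
  attr(out, "exit_dir") <- dir
  out
}

# number of nucleotides on a strand
strand_nt <- function(s) sum(is_nucleotide_glyph(s$glyphs))

# sequence (nucleotide glyphs only)
strand_seq <- function(s) paste(s$glyphs[is_nucleotide_glyph(s$glyphs)], collapse = "")

.FLIP_H_GLYPH <- c("\u256d" = "\u256e", "\u256e" = "\u256d",
                   "\u2570" = "\u256f", "\u256f" = "\u2570")
.FLIP_V_GLYPH <- c("\u256d" = "\u2570", "\u2570" = "\u256d",
                   "\u256e" = "\u256f", "\u256f" = "\u256e")
.FLIP_H_DIR <- c(right = "left", left = "right", up = "up", down = "down")
.FLIP_V_DIR <- c(right = "right", left = "left", up = "down", down = "up")

# mirror a strand inside a bounding box of the given extents (0-based, inclusive)
flip_strand <- function(s, axis = c("h", "v"), max_row, max_col) {
  axis <- match.arg(axis)
  g <- s$glyphs
  if (axis == "h") {
    sw <- .FLIP_H_GLYPH[g]; g <- ifelse(is.na(sw), g, sw)
    start <- c(s$start[1], max_col - s$start[2])
    dir <- .FLIP_H_DIR[[s$direction]]
  } else {
    sw <- .FLIP_V_GLYPH[g]; g <- ifelse(is.na(sw), g, sw)
    start <- c(max_row - s$start[1], s$start[2])
    dir <- .FLIP_V_DIR[[s$direction]]
  }
  strand(unname(g), start, dir, poses = s$poses)
}
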