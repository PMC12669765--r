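#' @title Origami: a 2D grid of motifs and its assembled blueprint
#' @description An origami is a list of grid rows, each an ordered west-to-east
#'   list of motifs; every grid row corresponds to one helix track (two glyph
#'   lines: top strand read west to east, complement east to west, with the
#'   orientation of individual motifs free to differ, e.g. on the flipped rows
#'   of a serpentine raster). Assembly lays the motifs out with per-row column
#'   cursors, verifies unique cell occupancy, stitches strand fragments at
#'   their junctions (a 3' exit connects to the 5' start on the adjacent cell
#'   in its travel direction), orders the resulting strands 5' to 3' and
#'   re-indexes all motif-local base pairs into a global layered pair map.
#'   Unmatched junctions facing empty cells become molecule termini; closed
#'   backbone cycles are nicked at the first fragment in reading order.
#' @name origami_assembly
NULL

#' Create an (empty) origami
#'
#' @param rows list of rows; each row is a list of motifs, west to east
#' @return an object of class `origami`
#' @export
origami <- function(rows = list()) {
  rows <- lapply(rows, function(r) if (inherits(r, "origami_motif")) list(r) else r)
  structure(list(rows = rows, cache = NULL), class = "origami")
}

#' Insert a motif into an origami grid
#'
#' @param x an `origami`
#' @param m an `origami_motif`
#' @param row 0-based grid row; rows are created as needed
#' @param col 0-based slot within the row; existing motifs at this slot and
#'   east of it shift one slot east. Defaults to appending at the row end.
#' @return the modified origami (assembly cache invalidated)
#' @export
place_motif <- function(x, m, row, col = NULL) {
  stopifnot(inherits(x, "origami"), inherits(m, "origami_motif"))
  row <- as.integer(row)
  if (row < 0L) stop("row must be >= 0")
  while (length(x$rows) < row + 1L) x$rows[[length(x$rows) + 1L]] <- list()
  r <- x$rows[[row + 1L]]
  if (is.null(col)) col <- length(r)
  col <- as.integer(col)
  if (col < 0L || col > length(r)) {
    stop("col must be in 0..", length(r), " for row ", row)
  }
  x$rows[[row + 1L]] <- append(r, list(m), after = col)
  x["cache"] <- list(NULL)
  x
}

#' Remove a motif from an origami grid
#'
#' @param x an `origami`
#' @param row,col 0-based grid row and slot
#' @return the modified origami; the row is compacted and trailing empty rows
#'   are dropped
#' @export
remove_motif <- function(x, row, col) {
  stopifnot(inherits(x, "origami"))
  row <- as.integer(row); col <- as.integer(col)
  if (row < 0L || row >= length(x$rows)) stop("no grid row ", row)
  r <- x$rows[[row + 1L]]
  if (col < 0L || col >= length(r)) {
    stop("empty slot: no motif at (row ", row, ", slot ", col, ")")
  }
  x$rows[[row + 1L]] <- r[-(col + 1L)]
  while (length(x$rows) > 0L && length(x$rows[[length(x$rows)]]) == 0L) {
    x$rows[[length(x$rows)]] <- NULL
  }
  x["cache"] <- list(NULL)
  x
}

#' Total nucleotides over all placed motifs
#' @param x an `origami`
#' @export
origami_nt <- function(x) {
  sum(vapply(unlist(x$rows, recursive = FALSE), motif_nt, integer(1)), 0L)
}

motif_rowspan <- function(m) as.integer(m$meta$rows_spanned %||% 1L)

# deterministic layout: repeatedly place the next motif of the grid row whose
# column cursor is smallest (ties: smallest row). A motif spanning several
# grid rows is placed at the largest cursor among them and advances them all.
layout_origami <- function(x) {
  n_rows <- length(x$rows)
  cursor <- rep(0L, max(n_rows, 1L))
  nxt <- rep(1L, n_rows)
  placements <- list()
  repeat {
    active <- which(nxt <= vapply(x$rows, length, integer(1)))
    if (length(active) == 0L) break
    r <- active[which.min(cursor[active])]
    m <- x$rows[[r]][[nxt[r]]]
    span <- motif_rowspan(m)
    rows_hit <- r:min(r + span - 1L, max(n_rows, r + span - 1L))
    while (length(cursor) < max(rows_hit)) cursor <- c(cursor, 0L)
    xcol <- max(cursor[rows_hit])
    ext <- motif_extents(m)
    placements[[length(placements) + 1L]] <- list(
      motif = m, grid_row = r - 1L, x = xcol, id = length(placements) + 1L)
    cursor[rows_hit] <- xcol + ext["max_col"] + 1L
    nxt[r] <- nxt[r] + 1L
  }
  placements
}

#' Assemble an origami into a blueprint
#'
#' @param x an `origami`
#' @return an object of class `origami_blueprint` with elements `grid`
#'   (character matrix of glyphs), `strands` (character vector of IUPAC
#'   constraint sequences, 5' to 3', ordered by the reading-order position of
#'   their 5' end), `pairs` (data.frame `i`, `j`, `layer`, `wobble` over
#'   global nucleotide indices), `n_nt`, `circular` (logical per strand:
#'   was this strand nicked from a closed cycle), and `nt` (per-nucleotide
#'   table: global index, glyph line, column, grid row, motif name/kind,
#'   dovetail-seam flag)
#' @export
assemble <- function(x) {
  stopifnot(inherits(x, "origami"))
  placements <- layout_origami(x)
  if (length(placements) == 0L) {
    return(structure(list(
      grid = matrix(character(0), 0, 0), strands = character(0),
      pairs = data.frame(i = integer(0), j = integer(0), layer = integer(0),
                         wobble = logical(0)),
      n_nt = 0L, circular = logical(0),
      nt = data.frame()), class = "origami_blueprint"))
  }

  # place every strand fragment on the global glyph grid
  frags <- list()
  for (p in placements) {
    offsets <- c(0L, cumsum(vapply(p$motif$strands, strand_nt, integer(1))))
    for (k in seq_along(p$motif$strands)) {
      w <- walk_strand(p$motif$strands[[k]])
      w$row <- w$row + 2L * p$grid_row
      w$col <- w$col + p$x
      frags[[length(frags) + 1L]] <- list(
        id = length(frags) + 1L, instance = p$id,
        motif_name = p$motif$name, motif_kind = p$motif$kind,
        walk = w, exit_dir = attr(w, "exit_dir"),
        nt_offset = offsets[k], n_nt = sum(w$is_nt))
    }
  }

  cells <- do.call(rbind, lapply(frags, function(f) {
    data.frame(row = f$walk$row, col = f$walk$col, frag = f$id,
               name = f$motif_name)
  }))
  key <- paste(cells$row, cells$col)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    other <- which(key == key[d])[1]
    stop("glyph collision at grid cell (", cells$row[d], ",", cells$col[d],
         ") between motif '", cells$name[other], "' and motif '",
         cells$name[d], "'")
  }
  occupied <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cells))) assign(key[i], cells$frag[i], envir = occupied)

  # junction stitching: exit of fragment f -> start of fragment g
  start_key <- vapply(frags, function(f) {
    paste(f$walk$row[1], f$walk$col[1], f$walk$dir_in[1])
  }, character(1))
  start_of <- stats::setNames(seq_along(frags), start_key)
  # a 3' exit slides across empty cells in its travel direction until it
  # meets an occupied cell: a matching 5' start connects (the gap is filled
  # with path glyphs), anything else is a junction mismatch; running off the
  # blueprint is a legal terminus
  max_row <- max(cells$row); max_col <- max(cells$col)
  next_frag <- rep(NA_integer_, length(frags))
  fill_cells <- list()
  for (f in frags) {
    last <- nrow(f$walk)
    dlt <- .DIR_DELTA[[f$exit_dir]]
    pos <- c(f$walk$row[last], f$walk$col[last])
    gap <- list()
    repeat {
      pos <- pos + dlt
      if (pos[1] < 0 || pos[2] < 0 || pos[1] > max_row || pos[2] > max_col) {
        break  # terminus at blueprint boundary
      }
      ckey <- paste(pos[1], pos[2])
      if (is.null(occupied[[ckey]])) {
        gap[[length(gap) + 1L]] <- pos
        next
      }
      g <- start_of[paste(pos[1], pos[2], f$exit_dir)]
      if (is.na(g)) {
        hit <- frags[[occupied[[ckey]]]]
        stop("junction mismatch: 3' end of motif '", f$motif_name,
             "' points into motif '", hit$motif_name, "' at grid cell (",
             pos[1], ",", pos[2], ") without a matching 5' junction")
      }
      next_frag[f$id] <- g
      if (length(gap) > 0L) {
        glyph <- if (f$exit_dir %in% c("left", "right")) "\u2500" else "\u2502"
        fill_cells[[length(fill_cells) + 1L]] <- data.frame(
          row = vapply(gap, `[`, integer(1), 1L),
          col = vapply(gap, `[`, integer(1), 2L),
          glyph = glyph)
      }
      break
    }
  }

  # chains: linear strands start at fragments nobody links to; remaining
  # fragments lie on closed cycles, nicked at their first fragment in
  # reading order
  has_pred <- rep(FALSE, length(frags))
  has_pred[next_frag[!is.na(next_frag)]] <- TRUE
  frag_pos <- t(vapply(frags, function(f) c(f$walk$row[1], f$walk$col[1]),
                       integer(2)))
  reading_order <- order(frag_pos[, 1], frag_pos[, 2])
  visited <- rep(FALSE, length(frags))
  chains <- list(); circular <- logical(0)

  trace_chain <- function(f0) {
    chain <- integer(0); f <- f0
    repeat {
      if (visited[f]) break
      visited[f] <<- TRUE
      chain <- c(chain, f)
      f <- next_frag[f]
      if (is.na(f) || f == f0) break
    }
    chain
  }
  for (f0 in reading_order[!has_pred[reading_order]]) {
    if (!visited[f0]) {
      chains[[length(chains) + 1L]] <- trace_chain(f0)
      circular <- c(circular, FALSE)
    }
  }
  for (f0 in reading_order) {
    if (!visited[f0]) {
      chains[[length(chains) + 1L]] <- trace_chain(f0)
      circular <- c(circular, TRUE)
    }
  }
  # 5'-end reading order across strands
  ord <- order(vapply(chains, function(ch) frag_pos[ch[1], 1], integer(1)),
               vapply(chains, function(ch) frag_pos[ch[1], 2], integer(1)))
  chains <- chains[ord]; circular <- circular[ord]

  # global nucleotide numbering + per-instance local->global maps
  inst_map <- list()
  nt_rows <- list()
  strands_seq <- character(0)
  gidx <- 0L
  for (s in seq_along(chains)) {
    seq_letters <- character(0)
    for (fid in chains[[s]]) {
      f <- frags[[fid]]
      w <- f$walk[f$walk$is_nt, , drop = FALSE]
      n <- nrow(w)
      if (n > 0L) {
        glb <- gidx + seq_len(n)
        imap <- inst_map[[as.character(f$instance)]] %||% integer(0)
        imap[f$nt_offset + seq_len(n)] <- glb
        inst_map[[as.character(f$instance)]] <- imap
        nt_rows[[length(nt_rows) + 1L]] <- data.frame(
          idx = glb, line = w$row, col = w$col,
          grid_row = w$row %/% 2L, strand = s,
          motif = f$motif_name, kind = f$motif_kind,
          instance = f$instance,
          local = f$nt_offset + seq_len(n),
          stringsAsFactors = FALSE)
        seq_letters <- c(seq_letters, w$glyph)
        gidx <- gidx + n
      }
    }
    strands_seq <- c(strands_seq, paste(seq_letters, collapse = ""))
  }
  nt <- do.call(rbind, nt_rows)

  # re-index motif-local pairs
  pr <- list()
  for (p in placements) {
    lp <- p$motif$pairs
    if (nrow(lp) == 0L) next
    imap <- inst_map[[as.character(p$id)]]
    seam <- p$motif$meta$seam_local %||% integer(0)
    pr[[length(pr) + 1L]] <- data.frame(
      i = imap[lp$i], j = imap[lp$j], layer = lp$layer, wobble = lp$wobble)
  }
  pairs <- if (length(pr)) do.call(rbind, pr) else
    data.frame(i = integer(0), j = integer(0), layer = integer(0),
               wobble = logical(0))
  if (nrow(pairs) > 0L) {
    swap <- pairs$i > pairs$j
    tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
    pairs <- assign_layers(pairs, strict = FALSE)
  }

  # dovetail seam flag (pair between the two pass-through strands, used by
  # the 3D builder to bend the merged duplex onto the inter-helix midline)
  nt$seam <- FALSE
  if (nrow(pairs) > 0L && !is.null(nt)) {
    line_of <- nt$line[order(nt$idx)]
    kindv <- nt$kind[order(nt$idx)]
    seam_pair <- kindv[pairs$i] == "dovetail" &
      abs(line_of[pairs$i] - line_of[pairs$j]) == 3L
    seam_idx <- c(pairs$i[seam_pair], pairs$j[seam_pair])
    nt$seam[nt$idx %in% seam_idx] <- TRUE
  }

  # glyph grid (including the connector fills)
  allc <- do.call(rbind, lapply(frags, function(f) f$walk[, c("row", "col", "glyph")]))
  if (length(fill_cells) > 0L) allc <- rbind(allc, do.call(rbind, fill_cells))
  grid <- matrix(" ", max(allc$row) + 1L, max(allc$col) + 1L)
  grid[cbind(allc$row + 1L, allc$col + 1L)] <- allc$glyph

  # per-junction dovetail offsets, for the 3D row-placement chain
  dts <- placements[vapply(placements, function(p) p$motif$kind == "dovetail",
                           logical(1))]
  dt_off <- if (length(dts)) {
    unique(do.call(rbind, lapply(dts, function(p) data.frame(
      junction = p$grid_row,
      offset = as.integer(p$motif$meta$offset_bp %||% 0L)))))
  } else data.frame(junction = integer(0), offset = integer(0))

  structure(list(grid = grid, strands = strands_seq, pairs = pairs,
                 n_nt = gidx, circular = circular,
                 nt = nt[order(nt$idx), ],
                 dovetail_offsets = dt_off),
            class = "origami_blueprint")
}

#' @export
print.origami <- function(x, ...) {
  n <- vapply(x$rows, length, integer(1))
  cat("<origami> ", length(x$rows), " grid row(s), ", sum(n), " motif(s), ",
      origami_nt(x), " nt\n", sep = "")
  invisible(x)
}

#' @export
print.origami_blueprint <- function(x, ...) {
  cat("<origami_blueprint> ", x$n_nt, " nt, ", length(x$strands),
      " strand(s), ", nrow(x$pairs), " pairs (",
      sum(x$pairs$layer > 0L), " pseudoknot)\n", sep = "")
  for (r in seq_len(nrow(x$grid))) {
    cat("  ", paste(x$grid[r, ], collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

#' Blueprint text rendering
#'
#' @param bp an `origami_blueprint`
#' @return character vector, one glyph line per grid row
#' @export
blueprint_lines <- function(bp) {
  apply(bp$grid, 1L, paste, collapse = "")
}

#' Write a blueprint text file
#'
#' UTF-8 glyph grid, one line per grid row; `#` header comment lines carry
#' strand count and nucleotide totals.
#'
#' @param bp an `origami_blueprint`
#' @param path output file
#' @export
write_blueprint <- function(bp, path) {
  header <- c(
    paste0("# origami blueprint: ", bp$n_nt, " nt, ", length(bp$strands),
           " strand(s), ", nrow(bp$pairs), " pairs"),
    paste0("# strands: ", paste(bp$strands, collapse = "&")))
  writeLines(c(header, blueprint_lines(bp)), path, useBytes = FALSE)
  invisible(path)
}

#' Read a blueprint text file
#'
#' Returns the glyph grid lines and the linearized strand constraints stored
#' in the header.
#'
#' @param path blueprint file
#' @return list with `lines` (glyph grid) and `strands` (character vector)
#' @export
read_blueprint <- function(path) {
  all_lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", all_lines, value = TRUE)
  strands <- character(0)
  sline <- grep("^# strands: ", hdr, value = TRUE)
  if (length(sline) == 1L) {
    strands <- strsplit(sub("^# strands: ", "", sline), "&", fixed = TRUE)[[1]]
  }
  list(lines = all_lines[!grepl("^#", all_lines)], strands = strands)
}
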