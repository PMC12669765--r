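#' @title Layered dot-bracket notation
#' @description Pseudoknotted secondary structure is written with one bracket
#'   alphabet per nesting layer: `()` for the nested (layer 0) structure, then
#'   `[]`, `{}`, `<>`, then letter pairs `Aa`, `Bb`, ... for further
#'   pseudoknot layers. `&` marks a strand break and occupies one character in
#'   both the structure and the aligned constraint string. `.` is unpaired.
#' @name dotbracket
#' @keywords internal
NULL

.BRACKET_OPEN  <- c("(", "[", "{", "<", LETTERS)
.BRACKET_CLOSE <- c(")", "]", "}", ">", letters)

max_pseudoknot_layers <- function() length(.BRACKET_OPEN) - 1L

#' Parse layered dot-bracket notation
#'
#' @param structure dot-bracket string, possibly with `&` strand breaks
#' @return list with `n` (number of nucleotide positions), `pairs` (data.frame
#'   `i`, `j`, `layer`; 1-based indices over nucleotide positions, `i < j`),
#'   and `breaks` (number of nucleotides before each strand break)
#' @export
parse_dotbracket <- function(structure) {
  ch <- chars(structure)
  known <- c(.BRACKET_OPEN, .BRACKET_CLOSE, ".", "&")
  bad <- setdiff(unique(ch), known)
  if (length(bad) > 0L) {
    stop("unknown structure character(s): ", paste(bad, collapse = " "))
  }
  idx <- cumsum(ch != "&")          # nucleotide index at each string position
  breaks <- idx[ch == "&"]
  if (any(breaks == 0L) || (length(ch) && ch[length(ch)] == "&")) {
    stop("strand break '&' at sequence boundary")
  }
  pr <- list()
  for (layer in seq_along(.BRACKET_OPEN)) {
    op <- .BRACKET_OPEN[layer]; cl <- .BRACKET_CLOSE[layer]
    stack <- integer(0)
    ii <- integer(0); jj <- integer(0)
    for (p in seq_along(ch)) {
      if (ch[p] == op) {
        stack <- c(stack, idx[p])
      } else if (ch[p] == cl) {
        if (length(stack) == 0L) {
          stop("unbalanced '", cl, "' at position ", p)
        }
        ii <- c(ii, stack[length(stack)]); jj <- c(jj, idx[p])
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L) stop("unbalanced '", op, "': ", length(stack), " unclosed")
    if (length(ii)) {
      pr[[length(pr) + 1L]] <- data.frame(i = ii, j = jj, layer = layer - 1L)
    }
  }
  pairs <- if (length(pr)) do.call(rbind, pr) else
    data.frame(i = integer(0), j = integer(0), layer = integer(0))
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  list(n = if (length(idx)) max(idx, 0L) else 0L, pairs = pairs, breaks = breaks)
}

#' Render pairs as layered dot-bracket notation
#'
#' @param n number of nucleotide positions
#' @param pairs data.frame with columns `i`, `j`, `layer`
#' @param breaks nucleotide counts before each strand break
#' @return dot-bracket string
#' @export
format_dotbracket <- function(n, pairs, breaks = integer(0)) {
  if (nrow(pairs) > 0L && max(pairs$layer) > max_pseudoknot_layers()) {
    stop("more pseudoknot layers (", max(pairs$layer),
         ") than available bracket alphabets (", max_pseudoknot_layers(), ")")
  }
  out <- rep(".", n)
  if (nrow(pairs) > 0L) {
    out[pairs$i] <- .BRACKET_OPEN[pairs$layer + 1L]
    out[pairs$j] <- .BRACKET_CLOSE[pairs$layer + 1L]
  }
  if (length(breaks) > 0L) {
    # insert '&' after the given nucleotide counts, right to left
    for (b in sort(breaks, decreasing = TRUE)) {
      out <- append(out, "&", after = b)
    }
  }
  paste(out, collapse = "")
}

pairs_cross <- function(i1, j1, i2, j2) {
  (i1 < i2 & i2 < j1 & j1 < j2) | (i2 < i1 & i1 < j2 & j2 < j1)
}

# any crossing pair inside one set?
any_crossing <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) {
    if (any(pairs_cross(pairs$i[a], pairs$j[a],
                        pairs$i[(a + 1L):n], pairs$j[(a + 1L):n]))) return(TRUE)
  }
  FALSE
}

#' Assign pseudoknot pairs to non-crossing bracket layers
#'
#' Layer-0 (secondary structure) pairs must already be non-crossing; pairs
#' flagged as pseudoknots are distributed greedily, in order of first
#' occurrence, onto the lowest pseudoknot layer on which they do not cross a
#' previously placed pair.
#'
#' @param pairs data.frame `i`, `j`, `layer` where `layer` 0 marks secondary
#'   structure and values >= 1 request a pseudoknot layer
#' @param strict when TRUE, crossing layer-0 pairs are an error; when FALSE
#'   (partial or exotic topologies where the linear order interleaves them)
#'   the first-seen non-crossing subset stays on layer 0 and the rest are
#'   promoted to pseudoknot layers
#' @return the same data.frame with final `layer` values
#' @keywords internal
assign_layers <- function(pairs, strict = TRUE) {
  if (nrow(pairs) == 0L) return(pairs)
  sec <- pairs[pairs$layer == 0L, , drop = FALSE]
  if (any_crossing(sec)) {
    if (strict) stop("crossing pairs within the nested (layer 0) structure")
    sec <- sec[order(sec$i), , drop = FALSE]
    keep <- logical(nrow(sec))
    for (r in seq_len(nrow(sec))) {
      kept <- sec[keep, , drop = FALSE]
      keep[r] <- !any(pairs_cross(sec$i[r], sec$j[r], kept$i, kept$j))
    }
    sec$layer[!keep] <- 1L
    pairs <- rbind(sec, pairs[pairs$layer > 0L, , drop = FALSE])
    sec <- pairs[pairs$layer == 0L, , drop = FALSE]
  }
  pk <- pairs[pairs$layer > 0L, , drop = FALSE]
  if (nrow(pk) == 0L) return(pairs)
  pk <- pk[order(pk$i), , drop = FALSE]
  layers <- list()   # per pseudoknot layer: data.frame of placed pairs
  final <- integer(nrow(pk))
  for (r in seq_len(nrow(pk))) {
    placed <- FALSE
    for (l in seq_along(layers)) {
      if (!any(pairs_cross(pk$i[r], pk$j[r], layers[[l]]$i, layers[[l]]$j))) {
        layers[[l]] <- rbind(layers[[l]], pk[r, c("i", "j")])
        final[r] <- l
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      layers[[length(layers) + 1L]] <- pk[r, c("i", "j")]
      final[r] <- length(layers)
    }
  }
  if (length(layers) > max_pseudoknot_layers()) {
    stop("more pseudoknot layers than available bracket alphabets")
  }
  pk$layer <- final
  out <- rbind(sec, pk)
  out <- out[order(out$i), , drop = FALSE]
  rownames(out) <- NULL
  out
}
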