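#' @title 3D model generation from ideal A-form helices
#' @description Every nucleotide of a design receives a pose: a position (nm),
#'   a unit base vector (backbone to base) and a unit stacking normal. Helix
#'   geometry uses ideal RNA A-form parameters (defaults: 0.281 nm rise and
#'   32.7 degrees twist per base pair, 1.15 nm backbone radius); helix rows of
#'   the blueprint are chained with one rigid frame per row, rotating the
#'   stacking direction at each inter-helix junction by a dihedral set by the
#'   junction's dovetail offset (180 degrees + offset x twist, wrapped), so
#'   alternating +/-5 offsets give a flat corrugated sheet and short +/-2
#'   offsets fold a second layer on top. Dovetail seam pairs are bent onto
#'   the midline between their two helix rows.
#' @name geometry3d
NULL

#' Ideal A-form helix parameters
#'
#' @param rise_per_bp axial rise per base pair, nm
#' @param twist_per_bp helical twist per base pair, degrees
#' @param helix_radius backbone radius, nm
#' @param inclination base-pair inclination, degrees (kept for completeness;
#'   the packaged geometry models base-pair planes perpendicular to the axis)
#' @param interhelix_spacing centre-to-centre distance of crossover-linked
#'   helices, nm (packaged crossover-geometry constant)
#' @return a `helix_params` list
#' @export
helix_params <- function(rise_per_bp = 0.281, twist_per_bp = 32.7,
                         helix_radius = 1.15, inclination = 0,
                         interhelix_spacing = 3.3) {
  if (rise_per_bp <= 0) stop("rise_per_bp must be > 0")
  if (twist_per_bp <= 0 || twist_per_bp >= 360) {
    stop("twist_per_bp must be in (0, 360)")
  }
  structure(list(rise_per_bp = rise_per_bp, twist_per_bp = twist_per_bp,
                 helix_radius = helix_radius, inclination = inclination,
                 interhelix_spacing = interhelix_spacing),
            class = "helix_params")
}

#' Orthonormal right-handed frame
#'
#' @param origin 3-vector, nm
#' @param axes 3x3 matrix, columns are the axis vectors
#' @return a `frame` object
#' @export
frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  axes <- as.matrix(axes)
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9) {
    stop("degenerate frame: axes are not orthonormal")
  }
  if (det(axes) < 0) stop("degenerate frame: left-handed axes")
  structure(list(origin = as.numeric(origin), axes = axes), class = "frame")
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' Pose lists for an ideal A-form helix
#'
#' Strand 1 runs 5' to 3' along +x, advancing one rise and one twist per base
#' pair; strand 2 is the antiparallel complement, its base vectors
#' anti-aligned with the partner's.
#'
#' @param n_bp number of base pairs (>= 1)
#' @param params [helix_params()]
#' @return list with `strand1` and `strand2`, each an `n_bp` x 9 pose matrix
#'   (position, base vector, normal vector), both in 5' to 3' order
#' @export
ideal_helix <- function(n_bp, params = helix_params()) {
  n <- as.integer(n_bp)
  if (is.na(n) || n < 1L) stop("n_bp must be a positive integer")
  cols <- 0:(n - 1L)
  th <- cols * params$twist_per_bp * pi / 180
  p1 <- cbind(cols * params$rise_per_bp,
              params$helix_radius * cos(th),
              params$helix_radius * sin(th),
              0, -cos(th), -sin(th),
              1, 0, 0)
  # strand 2: nucleotide k pairs strand-1 nucleotide n-1-k, phase pi across
  c2 <- rev(cols)
  t2 <- c2 * params$twist_per_bp * pi / 180 + pi
  p2 <- cbind(c2 * params$rise_per_bp,
              params$helix_radius * cos(t2),
              params$helix_radius * sin(t2),
              0, -cos(t2), -sin(t2),
              -1, 0, 0)
  list(strand1 = p1, strand2 = p2)
}

#' Frame at the 3' (high-x) end of an ideal helix
#'
#' The frame a continuation helix must be attached to so that rise and twist
#' stay continuous.
#'
#' @param n_bp base pairs already laid down
#' @param params [helix_params()]
#' @return a [frame()]
#' @export
helix_exit_frame <- function(n_bp, params = helix_params()) {
  frame(c(n_bp * params$rise_per_bp, 0, 0), rot_x(n_bp * params$twist_per_bp))
}

#' Rigidly attach a motif conformation to a global frame
#'
#' Computes the unique rotation + translation mapping the motif entry frame
#' onto `global_exit` and applies it to all poses and the motif exit frame.
#' Pure isometry: pairwise distances are preserved exactly.
#'
#' @param poses n x 9 pose matrix
#' @param entry,exit motif-local [frame()]s
#' @param global_exit the global frame to attach the entry to
#' @return list with transformed `poses` and the new global `exit` frame
#' @export
attach_poses <- function(poses, entry, exit, global_exit) {
  stopifnot(inherits(entry, "frame"), inherits(exit, "frame"),
            inherits(global_exit, "frame"))
  R <- global_exit$axes %*% t(entry$axes)
  shift <- function(p) as.numeric(global_exit$origin + R %*% (p - entry$origin))
  out <- poses
  if (nrow(poses) > 0L) {
    out[, 1:3] <- t(apply(poses[, 1:3, drop = FALSE], 1L, shift))
    out[, 4:6] <- poses[, 4:6, drop = FALSE] %*% t(R)
    out[, 7:9] <- poses[, 7:9, drop = FALSE] %*% t(R)
  }
  new_exit <- frame(shift(exit$origin), R %*% exit$axes)
  list(poses = out, exit = new_exit)
}

# wrapped inter-helix dihedral for a signed dovetail offset
dovetail_dihedral <- function(offset_bp, params = helix_params()) {
  tau <- 180 + offset_bp * params$twist_per_bp
  ((tau + 180) %% 360) - 180
}

#' Entry/exit frames of a dovetail crossover
#'
#' The exit frame places the partner helix at the packaged inter-helix
#' spacing, rotated about the shared helix axis by the offset-dependent
#' dihedral; the dihedral is antisymmetric in the offset sign (mirror
#' rotation), and offset 0 gives parallel axes.
#'
#' @param offset_bp signed dovetail offset
#' @param params [helix_params()]
#' @return list of [frame()]s `entry` and `exit`
#' @export
crossover_frames <- function(offset_bp, params = helix_params()) {
  if (abs(offset_bp) * params$twist_per_bp >= 360) {
    stop("unsupported dovetail offset ", offset_bp)
  }
  tau <- dovetail_dihedral(offset_bp, params)
  R <- rot_x(tau)
  step <- params$interhelix_spacing * as.numeric(R %*% c(0, -1, 0))
  list(entry = frame(), exit = frame(step, R))
}

#' Build the 3D conformation of an origami
#'
#' Deterministic rigid-body model: helix-row frames are chained through the
#' per-junction dovetail dihedrals, every nucleotide is placed on its row's
#' ideal helix at its blueprint column (top line at phase 0, bottom line at
#' phase 180 degrees), and dovetail seam nucleotides are bent onto the
#' midline between their two rows. Motifs without library geometry fall back
#' to this helical default.
#'
#' @param x an `origami` or `origami_blueprint`
#' @param params [helix_params()]
#' @param sequence optional concrete sequence (single string, strand breaks
#'   ignored) carried into the conformation for file export
#' @return an `origami_conformation`: `poses` (n x 9 matrix), `strand_nt`
#'   (nucleotides per strand), `sequences`, `pairs`, `box` (nm)
#' @export
build_conformation <- function(x, params = helix_params(), sequence = NULL) {
  bp <- if (inherits(x, "origami_blueprint")) x else assemble(x)
  n <- bp$n_nt
  if (n == 0L) {
    return(structure(list(poses = matrix(numeric(0), 0, 9),
                          strand_nt = integer(0), sequences = character(0),
                          pairs = bp$pairs, box = c(0, 0, 0), params = params),
                     class = "origami_conformation"))
  }
  nt <- bp$nt
  rows <- sort(unique(nt$grid_row))
  n_rows <- max(rows) + 1L

  # chain row frames through the junction dihedrals
  tau <- rep(0, max(n_rows - 1L, 0L))
  if (nrow(bp$dovetail_offsets %||% data.frame()) > 0L) {
    for (r in seq_len(nrow(bp$dovetail_offsets))) {
      j <- bp$dovetail_offsets$junction[r] + 1L
      if (j <= length(tau)) {
        tau[j] <- dovetail_dihedral(bp$dovetail_offsets$offset[r], params)
      }
    }
  }
  gamma <- cumsum(c(0, tau))          # cumulative stacking direction per row
  origin <- matrix(0, n_rows, 3)
  for (r in seq_len(n_rows - 1L)) {
    u <- as.numeric(rot_x(gamma[r + 1L]) %*% c(0, -1, 0))
    origin[r + 1L, ] <- origin[r, ] + params$interhelix_spacing * u
  }

  pose_at <- function(orig, gam, col, top) {
    th <- col * params$twist_per_bp * pi / 180 + if (top) 0 else pi
    A <- rot_x(gam)
    radial <- as.numeric(A %*% c(0, cos(th), sin(th)))
    axis <- c(1, 0, 0)
    c(orig + c(col * params$rise_per_bp, 0, 0) + params$helix_radius * radial,
      -radial,
      if (top) axis else -axis)
  }

  poses <- matrix(NA_real_, n, 9)
  for (k in seq_len(nrow(nt))) {
    r <- nt$grid_row[k]
    top <- nt$line[k] %% 2L == 0L
    if (isTRUE(nt$seam[k])) {
      r2 <- if (top) r + 1L else r - 1L
      orig <- (origin[r + 1L, ] + origin[r2 + 1L, ]) / 2
      gam <- (gamma[r + 1L] + gamma[r2 + 1L]) / 2
    } else {
      orig <- origin[r + 1L, ]
      gam <- gamma[r + 1L]
    }
    poses[nt$idx[k], ] <- pose_at(orig, gam, nt$col[k], top)
  }

  seqs <- bp$strands
  if (!is.null(sequence)) {
    sequence <- gsub("&", "", sequence, fixed = TRUE)
    if (nchar(sequence) != n) {
      stop("sequence length ", nchar(sequence), " does not match design (",
           n, " nt)")
    }
    lens <- nchar(seqs)
    off <- cumsum(c(0, lens))
    seqs <- vapply(seq_along(lens), function(s) {
      substr(sequence, off[s] + 1L, off[s] + lens[s])
    }, character(1))
  }
  ext <- apply(poses[, 1:3, drop = FALSE], 2L, function(v) diff(range(v)))
  structure(list(poses = poses, strand_nt = nchar(bp$strands),
                 sequences = seqs, pairs = bp$pairs,
                 box = pmax(1.5 * ext, 1), params = params),
            class = "origami_conformation")
}

#' @export
print.origami_conformation <- function(x, ...) {
  cat("<origami_conformation> ", nrow(x$poses), " nucleotides, ",
      length(x$strand_nt), " strand(s)\n", sep = "")
  if (nrow(x$poses) > 0L) {
    e <- bounding_extents(x)
    cat("  principal extents (nm): ", paste(sprintf("%.1f", e), collapse = " x "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Principal-axis bounding extents
#'
#' Extents of the nucleotide positions along the principal axes of the point
#' cloud, in decreasing order.
#'
#' @param conf an `origami_conformation`
#' @return numeric length-3 vector (nm), descending
#' @export
bounding_extents <- function(conf) {
  P <- conf$poses[, 1:3, drop = FALSE]
  if (nrow(P) == 0L) stop("empty conformation")
  if (nrow(P) == 1L) return(c(0, 0, 0))
  C <- sweep(P, 2L, colMeans(P))
  V <- svd(C)$v
  proj <- C %*% V
  sort(apply(proj, 2L, function(v) diff(range(v))), decreasing = TRUE)
}

#' Identify helix tracks in a conformation
#'
#' Groups base pairs into maximal runs of consecutive pairs whose midpoints
#' advance continuously, then merges runs lying on the same straight line
#' (parallel axes within an angular tolerance and a small perpendicular
#' offset). Pseudoknot (kissing) pairs are excluded.
#'
#' @param conf an `origami_conformation`
#' @param min_run_bp shortest run kept as a helix track (default 6, which
#'   excludes dovetail seam stems of typical length)
#' @param angle_tol_deg collinearity tolerance between run axes
#' @param offset_tol_nm largest perpendicular distance for merging runs
#' @return data.frame with one row per track: `n_bp`, centroid (`x`, `y`,
#'   `z`) and axis direction (`ax`, `ay`, `az`)
#' @export
helix_tracks <- function(conf, min_run_bp = 6L, angle_tol_deg = 10,
                         offset_tol_nm = 1.5) {
  pr <- conf$pairs
  pr <- pr[pr$layer == 0L, , drop = FALSE]
  if (nrow(pr) == 0L) {
    return(data.frame(n_bp = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), ax = numeric(0), ay = numeric(0),
                      az = numeric(0)))
  }
  mid <- (conf$poses[pr$i, 1:3, drop = FALSE] +
            conf$poses[pr$j, 1:3, drop = FALSE]) / 2
  ord <- order(pr$i)
  mid <- mid[ord, , drop = FALSE]
  step <- 2 * conf$params$rise_per_bp
  # contiguous runs of pair midpoints
  runs <- list(); cur <- 1L
  if (nrow(mid) > 1L) {
    for (k in 2:nrow(mid)) {
      if (sqrt(sum((mid[k, ] - mid[k - 1L, ])^2)) > step) {
        runs[[length(runs) + 1L]] <- cur:(k - 1L); cur <- k
      }
    }
  }
  runs[[length(runs) + 1L]] <- cur:nrow(mid)
  runs <- Filter(function(r) length(r) >= 3L, runs)
  if (length(runs) == 0L) {
    return(data.frame(n_bp = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), ax = numeric(0), ay = numeric(0),
                      az = numeric(0)))
  }
  info <- lapply(runs, function(r) {
    M <- mid[r, , drop = FALSE]
    C <- sweep(M, 2L, colMeans(M))
    ax <- svd(C)$v[, 1]
    if (ax[1] < 0) ax <- -ax
    list(n = length(r), centroid = colMeans(M), axis = ax)
  })
  # merge runs on the same line
  track <- seq_along(info)
  cosmin <- cos(angle_tol_deg * pi / 180)
  for (a in seq_along(info)) {
    for (b in seq_len(a - 1L)) {
      if (track[b] != track[b]) next
      ca <- info[[a]]; cb <- info[[b]]
      if (abs(sum(ca$axis * cb$axis)) < cosmin) next
      d <- cb$centroid - ca$centroid
      perp <- d - sum(d * ca$axis) * ca$axis
      if (sqrt(sum(perp^2)) <= offset_tol_nm) {
        track[track == track[a]] <- track[b]
      }
    }
  }
  agg <- lapply(unique(track), function(tk) {
    members <- which(track == tk)
    n <- sum(vapply(info[members], function(i) i$n, integer(1)))
    w <- vapply(info[members], function(i) i$n, integer(1))
    ctr <- colSums(t(vapply(info[members], function(i) i$centroid,
                            numeric(3))) * w) / sum(w)
    data.frame(n_bp = n, x = ctr[1], y = ctr[2], z = ctr[3],
               ax = info[[members[1]]]$axis[1],
               ay = info[[members[1]]]$axis[2],
               az = info[[members[1]]]$axis[3])
  })
  out <- do.call(rbind, agg)
  out <- out[out$n_bp >= min_run_bp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count helix tracks
#'
#' @param conf an `origami_conformation`
#' @param min_run_bp shortest paired run counted as a helix
#' @return integer number of distinct helix tracks
#' @export
count_helices <- function(conf, min_run_bp = 6L) {
  nrow(helix_tracks(conf, min_run_bp = min_run_bp))
}

#' Advisory steric clash count
#'
#' Number of nucleotide position pairs closer than `threshold_nm` that are
#' neither paired nor backbone neighbours. Clashes are reported, never
#' resolved: rigid concatenation can over-pack and the intrinsic flexibility
#' of RNA is expected to relax such contacts.
#'
#' @param conf an `origami_conformation`
#' @param threshold_nm contact distance (default 0.5 nm)
#' @return integer
#' @export
clash_count <- function(conf, threshold_nm = 0.5) {
  P <- conf$poses[, 1:3, drop = FALSE]
  n <- nrow(P)
  if (n < 2L) return(0L)
  d <- as.matrix(stats::dist(P))
  close <- which(d < threshold_nm & upper.tri(d), arr.ind = TRUE)
  if (nrow(close) == 0L) return(0L)
  neighbours <- abs(close[, 1] - close[, 2]) == 1L
  pk <- paste(pmin(close[, 1], close[, 2]), pmax(close[, 1], close[, 2]))
  paired <- pk %in% paste(conf$pairs$i, conf$pairs$j)
  sum(!neighbours & !paired)
}
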