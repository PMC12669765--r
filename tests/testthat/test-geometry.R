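test_that("ideal helices satisfy the closed-form rise/twist laws", {
  p <- helix_params()
  h <- ideal_helix(11, p)
  # axial end-to-end distance of strand 1 = (n-1) x rise
  expect_equal(h$strand1[11, 1] - h$strand1[1, 1], 10 * p$rise_per_bp,
               tolerance = 1e-9)
  # successive base vectors rotate by the twist about the axis
  for (k in 1:10) {
    v1 <- h$strand1[k, 5:6]; v2 <- h$strand1[k + 1, 5:6]
    ang <- acos(pmin(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))) * 180 / pi
    expect_equal(ang, p$twist_per_bp, tolerance = 1e-6)
  }
  # unit, orthogonal orientation vectors
  expect_equal(max(abs(rowSums(h$strand1[, 4:6]^2) - 1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(rowSums(h$strand1[, 4:6] * h$strand1[, 7:9]))), 0,
               tolerance = 1e-6)
  # paired bases face each other: base vectors anti-aligned
  for (k in 1:11) {
    expect_equal(sum(h$strand1[k, 4:6] * h$strand2[11 - k + 1, 4:6]), -1,
                 tolerance = 1e-9)
  }
  # single pair: zero axial extent
  h1 <- ideal_helix(1, p)
  expect_equal(nrow(h1$strand1), 1L)
  expect_error(ideal_helix(0), "positive")
})

test_that("attach is a rigid isometry and identity on the identity frame", {
  set.seed(7)
  poses <- cbind(matrix(rnorm(30), 10, 3), t(replicate(10, c(1, 0, 0))),
                 t(replicate(10, c(0, 1, 0))))
  id <- frame()
  out <- attach_poses(poses, id, helix_exit_frame(5), id)
  expect_equal(out$poses, poses, tolerance = 1e-12)

  # random target frame: all pairwise distances preserved within 1e-9
  ang <- 77.7
  target <- frame(c(1, -2, 3), rot_x(ang))
  moved <- attach_poses(poses, id, helix_exit_frame(5), target)$poses
  d0 <- dist(poses[, 1:3]); d1 <- dist(moved[, 1:3])
  expect_equal(max(abs(d0 - d1)), 0, tolerance = 1e-9)

  expect_error(frame(axes = matrix(0, 3, 3)), "degenerate|orthonormal")
})

test_that("two concatenated 5-bp stems reproduce a 10-bp ideal helix", {
  p <- helix_params()
  h5 <- ideal_helix(5, p)
  h10 <- ideal_helix(10, p)
  second <- attach_poses(rbind(h5$strand1, h5$strand2), frame(),
                         helix_exit_frame(5, p), helix_exit_frame(5, p))
  first <- rbind(h5$strand1, h5$strand2)
  # strand-1 poses: first five then next five
  got1 <- rbind(first[1:5, ], second$poses[1:5, ])
  expect_equal(got1, h10$strand1, tolerance = 1e-6)
  got2 <- rbind(second$poses[6:10, ], first[6:10, ])
  expect_equal(got2, h10$strand2, tolerance = 1e-6)
})

test_that("crossover frames respect spacing and sign antisymmetry", {
  p <- helix_params()
  f0 <- crossover_frames(0, p)
  expect_equal(sqrt(sum(f0$exit$origin^2)), p$interhelix_spacing,
               tolerance = 1e-9)
  # parallel helix axes: the shared axis is preserved exactly
  expect_equal(f0$exit$axes[, 1], c(1, 0, 0), tolerance = 1e-9)
  expect_equal(abs(sum(f0$exit$axes[, 2] * c(0, 1, 0))), 1, tolerance = 1e-9)
  fp <- crossover_frames(3, p); fm <- crossover_frames(-3, p)
  expect_equal(origamir:::dovetail_dihedral(3, p),
               -origamir:::dovetail_dihedral(-3, p))
  expect_equal(fp$exit$axes, t(fm$exit$axes), tolerance = 1e-9)
  expect_error(crossover_frames(20), "unsupported")
})

test_that("a pure stem conformation matches the ideal-helix oracle", {
  p <- helix_params()
  conf <- build_conformation(origami(list(list(stem(11)))), p)
  h <- ideal_helix(11, p)
  expect_equal(conf$poses, rbind(h$strand1, h$strand2), tolerance = 1e-6)
})

test_that("paired nucleotides sit within the pairing distance", {
  for (o in list(make_simple_origami(2, dovetails = 3L),
                 make_simple_origami(3, kl_columns = 1))) {
    conf <- build_conformation(o)
    pr <- conf$pairs[conf$pairs$layer == 0L, ]
    d <- sqrt(rowSums((conf$poses[pr$i, 1:3] - conf$poses[pr$j, 1:3])^2))
    expect_true(all(d < 2 * conf$params$helix_radius + 1e-6))
  }
})

test_that("conformations are deterministic and conserve pose counts", {
  o <- demo_rect_10h_3x()
  bp <- assemble(o)
  c1 <- build_conformation(bp)
  expect_equal(nrow(c1$poses), 2501L)
  c2 <- build_conformation(bp)
  expect_identical(c1$poses, c2$poses)
  # empty origami
  e <- build_conformation(origami())
  expect_equal(nrow(e$poses), 0L)
})

test_that("bounding extents follow closed forms and degenerate cases", {
  p <- helix_params()
  conf <- build_conformation(origami(list(list(stem(40)))), p)
  e <- bounding_extents(conf)
  # largest extent ~ (n-1) x rise (plus sub-radius transverse wobble)
  expect_equal(e[1], 39 * p$rise_per_bp, tolerance = 0.1)
  one <- conf; one$poses <- conf$poses[1, , drop = FALSE]
  expect_equal(bounding_extents(one), c(0, 0, 0))
  empty <- conf; empty$poses <- conf$poses[0, , drop = FALSE]
  expect_error(bounding_extents(empty), "empty")
})

test_that("helix counting identifies tracks and ignores unpaired strands", {
  p <- helix_params()
  one <- build_conformation(origami(list(list(stem(11)))), p)
  expect_equal(count_helices(one), 1L)
  polyu <- build_conformation(
    origami(list(list(from_structure(strrep(".", 30), strrep("U", 30))))), p)
  expect_equal(count_helices(polyu), 0L)
  two <- build_conformation(make_simple_origami(2, dovetails = 3L), p)
  expect_equal(count_helices(two), 2L)
})

test_that("oxDNA files round-trip within format precision", {
  o <- origami(list(list(transform_motif(tetraloop(), "rotate_180"), stem(4),
                         tetraloop())))
  conf <- build_conformation(o, sequence = strrep("A", 16))
  top <- withr::local_tempfile(fileext = ".top")
  dat <- withr::local_tempfile(fileext = ".dat")
  write_oxdna(conf, top, dat)
  back <- read_oxdna(top, dat)
  expect_equal(max(abs(back$poses[, 1:3] - conf$poses[, 1:3])), 0,
               tolerance = 1e-5)
  expect_equal(max(abs(back$poses[, 4:9] - conf$poses[, 4:9])), 0,
               tolerance = 1e-7)
  expect_identical(back$sequences, conf$sequences)
  # configuration line count = nucleotides + 3 header lines
  expect_equal(length(readLines(dat)), nrow(conf$poses) + 3L)
  # topology strand count matches the design
  expect_equal(length(back$strand_nt), length(conf$strand_nt))

  # malformed files diagnose the line
  writeLines(c("16 1 5->3", strrep("A", 16)), top)
  bad <- readLines(dat); bad[7] <- "oops"
  writeLines(bad, dat)
  expect_error(read_oxdna(top, dat), "line 7")
})

test_that("oxRNA setup emits a deterministic, override-respecting bundle", {
  conf <- build_conformation(origami(list(list(stem(6)))))
  d1 <- withr::local_tempdir()
  files <- oxrna_setup(conf, "relax", d1, overrides = c(T = "25C"))
  expect_length(files, 3L)
  inp <- readLines(files[3])
  expect_true("T = 25C" %in% inp)
  # emitted topology identical to write_oxdna output
  top2 <- withr::local_tempfile(); dat2 <- withr::local_tempfile()
  write_oxdna(conf, top2, dat2)
  expect_identical(readLines(files[1]), readLines(top2))
})

test_that("advisory clash count is exposed, not enforced", {
  conf <- build_conformation(demo_filament_tile())
  expect_true(clash_count(conf) >= 0L)
})
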