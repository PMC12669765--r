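capped_row <- function(middle) {
  c(list(transform_motif(tetraloop(), "rotate_180")), middle,
    list(tetraloop()))
}

test_that("a capped stem assembles to the expected strand and structure", {
  o <- origami(list(capped_row(list(stem(4)))))
  bp <- assemble(o)
  expect_equal(bp$n_nt, 16L)
  expect_length(bp$strands, 1L)
  tg <- to_target(bp)
  expect_identical(tg$constraints, "NNNNUUCGNNNNUUCG")
  expect_identical(tg$structure, "((((....))))....")
})

test_that("a stem capped at one end gives the uncapped-terminus target", {
  o <- origami(list(list(stem(4), tetraloop())))
  tg <- to_target(o)
  expect_identical(tg$constraints, "NNNNUUCGNNNN")
  expect_identical(tg$structure, "((((....))))")
})

test_that("a 5-bp stem alone yields 10 nucleotides in two facing runs", {
  bp <- assemble(origami(list(list(stem(5)))))
  expect_equal(bp$n_nt, 10L)
  expect_length(bp$strands, 2L)
  expect_true(all(nchar(bp$strands) == 5L))
})

test_that("place and remove are inverse operations", {
  o <- origami(list(capped_row(list(stem(4)))))
  o2 <- remove_motif(place_motif(o, stem(6), row = 0, col = 1), 0, 1)
  expect_identical(o, o2)
  # remove then re-place: byte-identical blueprint
  o3 <- place_motif(remove_motif(o, 0, 1), stem(4), 0, 1)
  expect_identical(blueprint_lines(assemble(o)), blueprint_lines(assemble(o3)))
})

test_that("removal edge cases behave as documented", {
  o <- origami(list(list(tetraloop())))
  expect_s3_class(assemble(remove_motif(o, 0, 0)), "origami_blueprint")
  expect_equal(assemble(remove_motif(o, 0, 0))$n_nt, 0L)
  expect_error(remove_motif(o, 0, 3), "empty slot")
  # two facing caps close into a single nicked loop (documented convention)
  oo <- remove_motif(origami(list(capped_row(list(stem(4))))), 0, 1)
  bp <- assemble(oo)
  expect_length(bp$strands, 1L)
  expect_true(bp$circular)
})

test_that("disconnected rows produce one strand each", {
  o <- origami(list(capped_row(list(stem(4))), capped_row(list(stem(6)))))
  bp <- assemble(o)
  expect_length(bp$strands, 2L)
})

test_that("mid-row kissing loops split the backbone and kiss across", {
  o <- origami(list(capped_row(list(stem(4), kissing_loop_180(), stem(4)))))
  bp <- assemble(o)
  expect_length(bp$strands, 2L)
  tg <- to_target(bp)
  expect_true(grepl("\\[", tg$structure))
  expect_equal(sum(bp$pairs$layer == 1L), 6L)
})

test_that("assembly is deterministic", {
  o <- make_simple_origami(3, kl_columns = 1)
  b1 <- assemble(o); b2 <- assemble(o)
  expect_identical(blueprint_lines(b1), blueprint_lines(b2))
  expect_identical(b1$pairs, b2$pairs)
  t1 <- to_target(o); t2 <- to_target(o)
  expect_identical(t1$constraints, t2$constraints)
  expect_identical(t1$structure, t2$structure)
})

test_that("junction mismatches and collisions raise informative errors", {
  # a dovetail with nothing on the second row dangles into empty space ->
  # its row-2 ports terminate, but a stem placed under a stem collides
  o <- origami(list(list(stem(4)), list()))
  o$rows[[2]] <- list(strand_clash <- stem(4))
  # same columns, same lines? second row occupies lines 2-3: no collision;
  # force one by placing a 2-row dovetail overlapping row 1's stem cells
  o2 <- origami(list(list(dovetail(2L, c(4, 4))),
                     list(stem(2))))
  expect_s3_class(assemble(o2), "origami_blueprint")
  # junction mismatch: a capped stem facing a stem's flank on the same line
  bad <- origami(list(list(stem(3), transform_motif(tetraloop(), "rotate_180")))
  )
  expect_error(assemble(bad), "junction mismatch")
})

test_that("nucleotide conservation holds for random small grids", {
  for (s in 1:10) {
    fx <- make_fixture(s, "small")
    bp <- assemble(fx$origami)
    expect_equal(bp$n_nt, origami_nt(fx$origami))
  }
})

test_that("pair maps are involutive and non-crossing within layers", {
  for (s in 1:8) {
    fx <- make_fixture(s, "medium")
    bp <- assemble(fx$origami)
    p <- bp$pairs
    expect_false(any(p$i == p$j))
    expect_false(anyDuplicated(c(p$i, p$j)) > 0)
    for (l in unique(p$layer)) {
      expect_false(origamir:::any_crossing(p[p$layer == l, , drop = FALSE]),
                   info = paste("seed", s, "layer", l))
    }
  }
})

test_that("targets are constraint/structure aligned with balanced brackets", {
  for (name in c("filament_tile", "rect_10h_3x", "droplet_y_motif")) {
    tg <- to_target(demo_design(name), name = name)
    expect_equal(nchar(tg$constraints), nchar(tg$structure), info = name)
    expect_true(brackets_balanced(tg$structure), info = name)
    # every paired position has a non-empty complementary intersection
    cons <- origamir:::chars(gsub("&", "", tg$constraints, fixed = TRUE))
    p <- tg$pairs
    ok <- mapply(function(i, j, w) origamir:::iupac_can_pair(cons[i], cons[j],
                                                             wobble = w),
                 p$i, p$j, p$wobble)
    expect_true(all(ok), info = name)
  }
})

test_that("the simple-origami generator meets its contracts", {
  expect_error(make_simple_origami(1), ">= 2")
  expect_error(make_simple_origami(4, dovetails = c(2, 2)), "one offset per")
  expect_error(make_simple_origami(2, dovetails = 9L, stem_length = 7),
               "exceeds stem segment length")
  # two helices, no kissing loops: analytic total
  o <- make_simple_origami(2, dovetails = 3L, kl_columns = 0, stem_length = 6)
  bp <- assemble(o)
  # 4 caps (16) + 4 stems of 6 bp (48) + one dovetail (2*3+8)
  expect_equal(bp$n_nt, 16L + 48L + 14L)
  expect_length(bp$strands, 1L)
})

test_that("demo designs match their published architecture", {
  bp <- assemble(demo_rect_10h_3x())
  expect_equal(bp$n_nt, 2501L)
  expect_length(bp$strands, 1L)

  bpf <- assemble(demo_filament_tile())
  expect_length(bpf$strands, 1L)
  # base layer of six helix tracks and a second layer of two
  expect_equal(length(unique(bpf$nt$grid_row)), 8L)

  bpd <- assemble(demo_droplet_y())
  expect_length(bpd$strands, 1L)
  # three palindromic kissing arms, five-uracil linkers, one Broccoli
  tgd <- to_target(bpd)
  expect_equal(length(gregexpr("AGGAUCC", tgd$constraints)[[1]]), 3L)
  expect_equal(length(gregexpr("UUUUU", tgd$constraints)[[1]]), 3L)
})

test_that("blueprint files round-trip through the package readers", {
  bp <- assemble(make_simple_origami(2, dovetails = 2L))
  path <- withr::local_tempfile(fileext = ".txt")
  write_blueprint(bp, path)
  back <- read_blueprint(path)
  expect_identical(back$lines, blueprint_lines(bp))
  expect_identical(back$strands, bp$strands)
})
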