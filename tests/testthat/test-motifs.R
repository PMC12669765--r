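library_motifs <- function() {
  list(stem(5), stem(4, "GGCC"), stem(10, wobble_fraction = 0.3),
       tetraloop("UUCG"), tetraloop("GAAA"),
       dovetail(0L), dovetail(3L, c(5L, 5L)), dovetail(-3L, c(5L, 5L)),
       kissing_loop_180(), aptamer("Broccoli"), aptamer("MS2_hairpin"))
}

test_that("stem constructor obeys its length, constraint and wobble contracts", {
  s5 <- stem(5)
  expect_equal(motif_nt(s5), 10L)
  expect_equal(motif_pairs(s5), 5L)
  expect_true(all(origamir:::motif_constraints(s5) == "N"))

  s <- stem(4, "GGCC")
  expect_identical(origamir:::strand_seq(s$strands[[2]]),
                   reverse_complement("GGCC"))
  expect_equal(sum(s$pairs$wobble), 0L)

  expect_equal(sum(stem(10, wobble_fraction = 0.3)$pairs$wobble), 3L)
  expect_error(stem(0), "positive")
  expect_error(stem(4, "GGC"), "length")

  # purity: same parameters, identical motifs
  expect_identical(stem(7, wobble_fraction = 0.2), stem(7, wobble_fraction = 0.2))
})

test_that("tetraloop caps carry a 4-nt unpaired loop", {
  tl <- tetraloop("UUCG")
  expect_equal(motif_nt(tl), 4L)
  expect_equal(motif_pairs(tl), 0L)
  expect_identical(paste(origamir:::motif_constraints(tl), collapse = ""),
                   "UUCG")
  expect_error(tetraloop("XXXX"), "unknown tetraloop")
})

test_that("dovetail pair and nucleotide counts follow its construction law", {
  # derived over offsets -3..3: pairs = |d| + 4, nucleotides = 2|d| + 8,
  # independent of sign
  for (d in -3:3) {
    m <- dovetail(d, c(5L, 5L))
    expect_equal(motif_pairs(m), abs(d) + 4L, info = paste("offset", d))
    expect_equal(motif_nt(m), 2L * abs(d) + 8L, info = paste("offset", d))
  }
  z <- dovetail(0L)
  expect_equal(motif_pairs(z), 4L)   # back-to-back crossovers, no seam
  expect_error(dovetail(6L, c(5L, 5L)), "too large")
  # sign is carried for the 3D dihedral
  expect_equal(dovetail(3L, c(5, 5))$meta$offset_bp, 3L)
  expect_equal(dovetail(-3L, c(5, 5))$meta$offset_bp, -3L)
})

test_that("kissing loops validate loop complementarity and topology", {
  kl <- kissing_loop_180()
  expect_equal(motif_nt(kl), 14L)
  expect_equal(motif_pairs(kl), 6L)
  expect_true(all(kl$pairs$layer == 1L))

  # palindromic core is self-complementary and accepted
  pal <- kissing_loop_spec("AGGAUCC", "AGGAUCC")
  expect_identical(pal$loop1, pal$loop2)
  expect_s3_class(kissing_loop_180(pal), "origami_motif")

  expect_error(kissing_loop_spec("AGGGGGG", "AGGGGGG"),
               "not reverse-complement compatible")

  term <- kissing_loop_180(kissing_loop_spec(topology = "branched"))
  expect_equal(motif_nt(term), 7L)
  expect_equal(motif_pairs(term), 0L)
})

test_that("aptamer catalog returns fixed-sequence motifs and lists names", {
  b <- aptamer("Broccoli")
  expect_equal(motif_nt(b), 49L)
  expect_false(any(origamir:::motif_constraints(b) == "N"))
  expect_error(aptamer("XYZ"), "Broccoli")
  expect_true(all(c("Broccoli", "MS2_hairpin") %in% aptamer_catalog()))
})

test_that("flips are involutions and rotate_180 is their composition", {
  for (m in library_motifs()) {
    expect_motif_equal(
      transform_motif(transform_motif(m, "flip_horizontal"), "flip_horizontal"),
      m)
    expect_motif_equal(
      transform_motif(transform_motif(m, "flip_vertical"), "flip_vertical"),
      m)
    hv <- transform_motif(transform_motif(m, "flip_horizontal"),
                          "flip_vertical")
    expect_motif_equal(transform_motif(m, "rotate_180"), hv)
    # conservation under flips
    for (op in c("flip_horizontal", "flip_vertical", "rotate_180")) {
      t <- transform_motif(m, op)
      expect_equal(motif_nt(t), motif_nt(m))
      expect_equal(motif_pairs(t), motif_pairs(m))
    }
  }
})

test_that("every catalog motif's pairs pass the IUPAC complement check", {
  for (m in library_motifs()) {
    cons <- origamir:::motif_constraints(m)
    p <- m$pairs
    if (nrow(p) == 0L) next
    ok <- mapply(function(i, j, w) origamir:::iupac_can_pair(cons[i], cons[j],
                                                             wobble = w),
                 p$i, p$j, p$wobble)
    expect_true(all(ok), info = m$name)
  }
})

test_that("custom motifs validate strand walks and pair compatibility", {
  # re-specifying stem(3) gives an equal motif
  s <- custom_motif(
    list(list(glyphs = "NNN", start = c(0, 0), direction = "right"),
         list(glyphs = "NNN", start = c(1, 2), direction = "left")),
    pairs = data.frame(i = 1:3, j = 6:4))
  expect_equal(motif_nt(s), motif_nt(stem(3)))
  expect_equal(s$pairs[, c("i", "j")], stem(3)$pairs[, c("i", "j")])

  # self-crossing path names the grid cell
  expect_error(
    custom_motif(list(list(
      glyphs = c("A", "A", "\u256e", "\u256f", "A", "\u2570", "A"),
      start = c(0, 0), direction = "right"))),
    "crosses itself")

  # fixed non-complementary pair
  expect_error(
    custom_motif(list(list(glyphs = "AC", start = c(0, 0),
                           direction = "right")),
                 pairs = data.frame(i = 1L, j = 2L)),
    "no complementary")
})

test_that("the Structure Converter round-trips and default-fills loops", {
  m <- from_structure("((..))", "GGAACC")
  expect_equal(motif_pairs(m), 2L)
  tg <- to_target(origami(list(list(m))))
  expect_identical(tg$constraints, "GGAACC")
  expect_identical(tg$structure, "((..))")

  expect_equal(motif_pairs(from_structure("......", "AAAAAA")), 0L)

  # absent sequence: N fill except packaged default tetraloop
  tg2 <- to_target(origami(list(list(from_structure("((((....))))")))))
  expect_identical(tg2$constraints, "NNNNUUCGNNNN")

  expect_error(from_structure("((..))", "GGAAC"), "length")
  expect_error(from_structure("((..)"), "unbalanced")
  expect_error(from_structure("((..))", "GGAACA"), "incompatible")

  # pseudoknot layers are preserved
  mk <- from_structure("((.[[..)).]]")
  expect_equal(sort(unique(mk$pairs$layer)), c(0L, 1L))
})

test_that("structure round-trip holds for random pseudoknot-free inputs", {
  set.seed(42)
  for (rep in 1:10) {
    db <- random_structure(sample(20:60, 1))
    p <- parse_dotbracket(db)
    seq <- vapply(seq_len(p$n), function(i) sample(c("A", "C", "G", "U"), 1),
                  character(1))
    # force complementary letters on pairs
    comp <- c(A = "U", U = "A", G = "C", C = "G")
    for (r in seq_len(nrow(p$pairs))) {
      seq[p$pairs$j[r]] <- comp[[seq[p$pairs$i[r]]]]
    }
    sq <- paste(seq, collapse = "")
    tg <- to_target(origami(list(list(from_structure(db, sq)))))
    expect_identical(tg$constraints, sq)
    expect_identical(tg$structure, db)
  }
})
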