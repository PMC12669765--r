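test_that("DNA templates obey the T7 +1 overlap rule", {
  r <- rna_to_dna("GGAAACC", "T7")
  expect_identical(r$coding_dna, "TAATACGACTCACTATAGGAAACC")
  expect_length(r$warnings, 0L)
  expect_identical(transcribe(r), "GGAAACC")
  expect_identical(r$template_strand,
                   origamir:::dna_reverse_complement(r$coding_dna))

  w <- rna_to_dna("AAUU", "T7")
  expect_length(w$warnings, 1L)
  expect_identical(transcribe(w), "AAUU")

  plain <- rna_to_dna("GGAAACC", "")
  expect_identical(plain$coding_dna, "GGAAACC")
  expect_identical(transcribe(plain), "GGAAACC")

  expect_error(rna_to_dna("GGXX"), "invalid nucleotide")
  expect_error(rna_to_dna(""), "non-empty")
})

test_that("reverse complement is an involution and transcription is exact", {
  set.seed(5)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
    expect_identical(transcribe(rna_to_dna(s, "T7")), s)
  }
})

test_that("gc_content matches hand counts", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AUAU"), 0.0)
  expect_equal(gc_content("GCAU"), 0.5)
  expect_error(gc_content(""), "empty")
})

test_that("IUPAC subsequence search reports all overlapping 0-based hits", {
  expect_identical(find_subsequence("GGAGG", "GG"), c(0L, 3L))
  expect_identical(find_subsequence("ACGU", "N"), 0:3)
  expect_identical(find_subsequence("AGAG", "R"), 0:3)
  expect_identical(find_subsequence("ACAC", "GG"), integer(0))
})

test_that("subsequence search equals the Biostrings IUPAC matcher", {
  set.seed(11)
  for (rep in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "U"), sample(6:12, 1),
                        replace = TRUE), collapse = "")
    query <- paste(sample(origamir:::iupac_letters(), sample(1:4, 1),
                          replace = TRUE), collapse = "")
    expect_identical(find_subsequence(seq, query),
                     as.integer(biostrings_subsequence(seq, query)),
                     info = paste(seq, query))
  }
})

test_that("dimer prediction equals the exhaustive oracle on short inputs", {
  s <- "ACGUACGUACGU"
  expect_equal(dimer_prediction(s, reverse_complement(s))$length, nchar(s))
  expect_equal(dimer_prediction("AAAA", "CCCC")$length, 0L)
  set.seed(3)
  for (rep in 1:30) {
    a <- paste(sample(c("A", "C", "G", "U"), sample(4:12, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(4:12, 1), replace = TRUE),
               collapse = "")
    expect_equal(dimer_prediction(a, b)$length,
                 brute_force_dimer_length(a, b), info = paste(a, b))
  }
  expect_error(dimer_prediction("", "AC"), "empty")
})

test_that("melting temperatures match the independent Biopython NN oracle", {
  set.seed(19)
  seqs <- vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(18:30, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  conds <- list(c(50, 0, 500), c(50, 2, 500), c(100, 0, 250))
  for (cd in conds) {
    ours <- vapply(seqs, melting_temperature, numeric(1),
                   cond = thermo_conditions(cd[1], cd[2], cd[3]))
    ref <- biopython_tm(seqs, cd[1], cd[2], cd[3])
    expect_lt(max(abs(ours - ref)), 0.01)
  }
})

test_that("Tm responds monotonically to length and GC content", {
  s <- "ACGTACGTACGTACGT"
  expect_gt(melting_temperature(strrep(s, 2)), melting_temperature(s))
  expect_lt(melting_temperature("AAAAAAAA"), melting_temperature("GGGGGGGG"))
  # appending a G-C pair at the 3' end does not decrease Tm
  expect_gte(melting_temperature(paste0(s, "G")), melting_temperature(s) - 1e-9)
  expect_error(melting_temperature("ACGT"), "too short")
  expect_error(thermo_conditions(nn_set = "zimm1960"), "unknown")
})

test_that("primer design anchors at template ends and hits the target Tm", {
  set.seed(2)
  rna <- paste(sample(c("A", "C", "G", "U"), 300, replace = TRUE,
                      prob = c(0.25, 0.25, 0.3, 0.2)), collapse = "")
  tpl <- rna_to_dna(paste0("G", rna), "T7")
  pp <- design_primers(tpl, target_tm = 66, tolerance = 1.5)
  expect_true(startsWith(tpl$coding_dna, pp$forward))
  expect_true(endsWith(tpl$coding_dna,
                       origamir:::dna_reverse_complement(pp$reverse)))
  expect_lte(abs(pp$tm_forward - 66), 1.5)
  expect_lte(abs(pp$tm_reverse - 66), 1.5)
  # pure recomputation: invariant to a second call
  expect_identical(pp, design_primers(tpl, target_tm = 66, tolerance = 1.5))
  # raising the target never shortens the primers
  pp2 <- design_primers(tpl, target_tm = 68, tolerance = 3)
  expect_gte(nchar(pp2$forward), nchar(pp$forward))
  expect_gte(nchar(pp2$reverse), nchar(pp$reverse))
  # unreachable target reports the best achievable
  expect_error(design_primers(tpl, target_tm = 120, tolerance = 1),
               "best achievable")
  expect_error(design_primers("ACGTACGT", 60), "too short")
})

test_that("FASTA round trips, detects the structure dialect, and warns on empty", {
  recs <- list(list(name = "a", sequence = "ACGU"),
               list(name = "b", sequence = "GGAACC", structure = "((..))"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- load_fasta(path)
  expect_equal(back, lapply(recs, function(r) {
    list(name = r$name, sequence = r$sequence, structure = r$structure)
  }))
  # the sequence+structure record feeds the Structure Converter directly
  m <- from_structure(back[[2]]$structure, back[[2]]$sequence)
  expect_equal(motif_pairs(m), 2L)

  writeLines(character(0), path)
  expect_warning(empty <- load_fasta(path), "empty")
  expect_length(empty, 0L)
  writeLines(c("ACGT"), path)
  expect_error(load_fasta(path), "line 1")
})
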