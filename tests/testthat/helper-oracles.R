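# Independent oracles used across the suite. Each reimplements the checked
# quantity from scratch (or delegates to an external reference tool), never
# calling the package code path it validates.

# exhaustive antiparallel dimer scan: longest diagonal complementary run
brute_force_dimer_length <- function(seq1, seq2) {
  comp <- c(A = "U", U = "A", G = "C", C = "G", T = "A")
  a <- strsplit(chartr("T", "U", toupper(seq1)), "")[[1]]
  b <- strsplit(chartr("T", "U", toupper(seq2)), "")[[1]]
  best <- 0L
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      run <- 0L
      while (i + run <= length(a) && j - run >= 1L &&
             comp[[a[i + run]]] == b[j - run]) {
        run <- run + 1L
      }
      best <- max(best, run)
    }
  }
  best
}

# IUPAC subsequence scan through Biostrings' fixed=FALSE matcher (0-based)
biostrings_subsequence <- function(seq, query) {
  hits <- Biostrings::matchPattern(
    Biostrings::RNAString(chartr("T", "U", toupper(query))),
    Biostrings::RNAString(chartr("T", "U", toupper(seq))),
    fixed = FALSE)
  BiocGenerics::start(hits) - 1L
}

# Biopython nearest-neighbor Tm (unified table, entropic salt correction);
# one python call per batch of sequences
biopython_tm <- function(seqs, mono_mM = 50, div_mM = 0, oligo_nM = 500) {
  script <- sprintf(paste0(
    "import sys\n",
    "from Bio.SeqUtils import MeltingTemp as mt\n",
    "for line in sys.stdin:\n",
    "    s = line.strip()\n",
    "    if not s: continue\n",
    "    comp = s.translate(str.maketrans('ACGT','TGCA'))[::-1]\n",
    "    print(mt.Tm_NN(s, nn_table=mt.DNA_NN3, dnac1=%f, dnac2=%f,\n",
    "          Na=%f, Mg=%f, saltcorr=5, selfcomp=(s == comp)))\n"),
    oligo_nM / 2, oligo_nM / 2, mono_mM, div_mM)
  out <- system2("python", c("-c", shQuote(script)),
                 input = seqs, stdout = TRUE)
  as.numeric(out)
}

# independent layered bracket-balance checker
brackets_balanced <- function(structure) {
  alph <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))
  ch <- strsplit(structure, "")[[1]]
  for (ab in alph) {
    depth <- 0L
    for (x in ch) {
      if (x == ab[1]) depth <- depth + 1L
      if (x == ab[2]) {
        depth <- depth - 1L
        if (depth < 0L) return(FALSE)
      }
    }
    if (depth != 0L) return(FALSE)
  }
  for (L in LETTERS) {
    if (sum(ch == L) != sum(ch == tolower(L))) return(FALSE)
  }
  TRUE
}

# random nested secondary structure with minimum hairpin loop 3
random_structure <- function(n, p_open = 0.4) {
  out <- character(n)
  open_at <- integer(0)
  for (k in seq_len(n)) {
    remaining <- n - k
    can_open <- remaining > length(open_at) + 4L
    can_close <- length(open_at) > 0L && k - open_at[length(open_at)] > 3L
    must_close <- length(open_at) >= remaining
    r <- stats::runif(1)
    if (must_close && can_close) {
      choice <- "close"
    } else if (can_open && r < p_open) {
      choice <- "open"
    } else if (can_close && r < 0.75) {
      choice <- "close"
    } else {
      choice <- "dot"
    }
    if (choice == "open") {
      open_at <- c(open_at, k); out[k] <- "("
    } else if (choice == "close") {
      out[k] <- ")"
      open_at <- open_at[-length(open_at)]
    } else out[k] <- "."
  }
  # close anything left over
  for (k in rev(seq_len(n))) {
    if (length(open_at) == 0L) break
    if (out[k] == "." && k - open_at[length(open_at)] > 3L) {
      out[k] <- ")"
      open_at <- open_at[-length(open_at)]
    }
  }
  if (length(open_at) > 0L) out[open_at] <- "."
  paste(out, collapse = "")
}

# random IUPAC constraint string compatible with a structure: paired
# positions stay N, a fraction of unpaired positions get fixed bases
random_constraints <- function(structure, p_fix = 0.15) {
  parsed <- parse_dotbracket(structure)
  ch <- rep("N", parsed$n)
  paired <- c(parsed$pairs$i, parsed$pairs$j)
  free <- setdiff(seq_len(parsed$n), paired)
  fix <- free[stats::runif(length(free)) < p_fix]
  ch[fix] <- sample(c("A", "C", "G", "U"), length(fix), replace = TRUE)
  paste(ch, collapse = "")
}

# split helix tracks into layers at the largest z gap and return the size of
# the largest layer (the base layer of a two-layer tile)
largest_layer_size <- function(tracks) {
  z <- sort(tracks$z)
  if (length(z) < 2L) return(length(z))
  gaps <- diff(z)
  cut <- which.max(gaps)
  if (gaps[cut] < 1.5) return(length(z))  # single layer
  max(cut, length(z) - cut)
}

expect_motif_equal <- function(a, b) {
  expect_equal(a$strands, b$strands)
  expect_equal(a$pairs, b$pairs)
}
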