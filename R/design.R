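#' @title Sequence design: constraint-respecting inverse folding
#' @description Turns a design target into a concrete RNA sequence. Free
#'   (ambiguous) positions are seeded randomly subject to their IUPAC
#'   constraint and pair complementarity (mutating a paired base always
#'   updates its partner), then greedily mutated to reduce a score combining
#'   the folding defect (base-pair distance between the oracle-predicted
#'   minimum-free-energy structure and the pseudoknot-masked target) and a
#'   sequence-symmetry penalty (repeated k-mers). Kissing-loop pseudoknots
#'   are enforced by hard complementarity and masked from the thermodynamic
#'   oracle. The oracle is pluggable; the packaged one shells out to
#'   ViennaRNA's RNAfold.
#' @name sequence_design
NULL

# run body with a private RNG stream
with_seed <- function(seed, body) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  body()
}

#' Count repeated k-mers
#'
#' Sequence-symmetry score: the number of k-mer occurrences in excess of one
#' (0 when all k-mers are unique).
#'
#' @param sequence character scalar
#' @param k k-mer length (default 8)
#' @return non-negative integer
#' @export
repeat_score <- function(sequence, k = 8L) {
  n <- nchar(sequence)
  if (n < k) return(0L)
  kmers <- substring(sequence, 1:(n - k + 1L), k:n)
  sum(pmax(table(kmers) - 1L, 0L))
}

#' ViennaRNA folding oracle
#'
#' Returns a function mapping an RNA sequence to its predicted
#' minimum-free-energy dot-bracket structure, backed by the RNAfold
#' executable.
#'
#' @return a function `function(sequence) -> structure`
#' @export
rnafold_oracle <- function() {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stop("folding oracle unavailable: RNAfold not found on PATH. ",
         "Install ViennaRNA or pass a custom oracle function.")
  }
  function(sequence) {
    out <- system2(exe, c("--noPS"), input = sequence, stdout = TRUE)
    strsplit(out[2], " ", fixed = TRUE)[[1]][1]
  }
}

# base-pair distance between two structures (symmetric difference of pair sets)
bp_distance <- function(db1, db2) {
  p1 <- parse_dotbracket(db1)$pairs
  p2 <- parse_dotbracket(db2)$pairs
  k1 <- paste(p1$i, p1$j); k2 <- paste(p2$i, p2$j)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# target structure with pseudoknot layers masked to unpaired
masked_structure <- function(spec) {
  p0 <- spec$pairs[spec$pairs$layer == 0L, , drop = FALSE]
  format_dotbracket(spec$n, p0, spec$breaks)
}

#' Design a sequence for a target
#'
#' @param spec a [target_spec()]
#' @param seed RNG seed; the result is a deterministic function of
#'   `(spec, seed, oracle)`
#' @param max_iterations mutation proposals before giving up
#' @param oracle optional folding oracle (see [rnafold_oracle()]); without an
#'   oracle only the sequence-symmetry penalty is minimised and the folding
#'   defect is `NA`
#' @param lambda weight of the repeat penalty per repeated k-mer occurrence
#' @param k repeat k-mer length
#' @return a `design_result`: `sequence`, `defect`, `repeat_score`, `seed`,
#'   `iterations`
#' @export
design_sequence <- function(spec, seed = 1L, max_iterations = 200L,
                            oracle = NULL, lambda = 0.1, k = 8L) {
  stopifnot(inherits(spec, "target_spec"))
  cons <- chars(gsub("&", "", spec$constraints, fixed = TRUE))
  n <- spec$n
  partner <- rep(NA_integer_, n)
  wobble_at <- rep(FALSE, n)
  p <- spec$pairs
  if (nrow(p) > 0L) {
    partner[p$i] <- p$j; partner[p$j] <- p$i
    wobble_at[p$i] <- p$wobble; wobble_at[p$j] <- p$wobble
  }
  fixed <- vapply(cons, function(x) length(iupac_bases(x)) == 1L, logical(1))
  # unsatisfiable fixed pairs are detected before iteration
  if (nrow(p) > 0L) {
    for (r in seq_len(nrow(p))) {
      if (fixed[p$i[r]] && fixed[p$j[r]] &&
          !iupac_can_pair(cons[p$i[r]], cons[p$j[r]], wobble = p$wobble[r])) {
        stop("unsatisfiable constraints: fixed pair ",
             cons[p$i[r]], "-", cons[p$j[r]], " at positions ",
             p$i[r], "-", p$j[r])
      }
    }
  }
  free_sites <- which(!fixed)
  # representative site per mutable group (a pair is mutated as a unit)
  groups <- unique(ifelse(!is.na(partner[free_sites]),
                          pmin(free_sites, partner[free_sites]), free_sites))

  sample1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]
  draw_group <- function(seq_l, g) {
    j <- partner[g]
    if (is.na(j)) {
      seq_l[g] <- sample1(iupac_bases(cons[g]))
    } else {
      a <- sample1(iupac_pairing_options(cons[g], cons[j], wobble_at[g]))
      b <- sample1(iupac_partners_of(a, cons[j], wobble_at[g]))
      seq_l[g] <- a; seq_l[j] <- b
    }
    seq_l
  }

  mask <- masked_structure(spec)
  mask <- gsub("&", "", mask, fixed = TRUE)
  score_of <- function(seq_l) {
    s <- paste(seq_l, collapse = "")
    rs <- repeat_score(s, k)
    defect <- if (is.null(oracle)) NA_real_ else bp_distance(oracle(s), mask)
    list(score = (if (is.na(defect)) 0 else defect) + lambda * rs,
         defect = defect, repeats = rs)
  }

  with_seed(seed, function() {
    seq_l <- cons
    seq_l[fixed & seq_l == "T"] <- "U"
    for (g in groups) seq_l <- draw_group(seq_l, g)
    cur <- score_of(seq_l)
    iter <- 0L
    if (length(groups) > 0L) {
      while (iter < max_iterations && cur$score > 0) {
        iter <- iter + 1L
        g <- sample1(groups)
        cand <- draw_group(seq_l, g)
        new <- score_of(cand)
        if (new$score < cur$score) {
          seq_l <- cand; cur <- new
        }
      }
    }
    structure(list(sequence = paste(seq_l, collapse = ""),
                   defect = cur$defect, repeat_score = cur$repeats,
                   seed = seed, iterations = iter,
                   score = cur$score, name = spec$name),
              class = "design_result")
  })
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> ", x$name, ": ", nchar(x$sequence), " nt, ",
      x$iterations, " iterations (seed ", x$seed, ")\n", sep = "")
  cat("  defect: ", if (is.na(x$defect)) "NA (no oracle)" else x$defect,
      ", repeated 8-mers: ", x$repeat_score, "\n", sep = "")
  invisible(x)
}

#' Thermodynamic folding-quality metrics
#'
#' Minimum-free-energy of the sequence, the equilibrium-ensemble frequency of
#' the (pseudoknot-masked) target structure, and the ensemble diversity (the
#' expected base-pair distance between two structures drawn from the
#' ensemble), computed with ViennaRNA's partition function.
#'
#' @param sequence RNA sequence
#' @param target_structure optional dot-bracket; pseudoknot layers are masked
#'   to unpaired before evaluation. Without a target, the frequency reported
#'   is that of the MFE structure itself.
#' @return list with `mfe_energy` (kcal/mol), `mfe_structure`,
#'   `ensemble_frequency`, `ensemble_diversity`
#' @export
folding_metrics <- function(sequence, target_structure = NULL) {
  if (!is.character(sequence) || nchar(sequence) == 0L) {
    stop("empty sequence")
  }
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stop("folding oracle unavailable: RNAfold not found on PATH")
  }
  wd <- tempfile("rnafold"); dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE), add = TRUE)
  out <- withr_dir(wd, function() {
    system2(exe, c("-p", "--noPS"), input = sequence, stdout = TRUE)
  })
  mfe_line <- out[2]
  mfe_structure <- strsplit(mfe_line, " ", fixed = TRUE)[[1]][1]
  mfe_energy <- as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", mfe_line))
  ens_line <- out[3]
  ens_energy <- as.numeric(sub(".*\\[(\\s*-?[0-9.]+)\\]\\s*$", "\\1", ens_line))
  stat_line <- grep("frequency of mfe structure", out, value = TRUE)
  freq_mfe <- as.numeric(sub(".*ensemble ([0-9.eE+-]+);.*", "\\1", stat_line))
  diversity <- as.numeric(sub(".*ensemble diversity ([0-9.eE+-]+).*", "\\1",
                              stat_line))
  kt <- 0.0019872 * 310.15   # kcal/mol at 37 C
  freq <- if (is.null(target_structure)) {
    freq_mfe
  } else {
    masked <- target_structure
    masked <- gsub("[^().&]", ".", masked)
    masked <- gsub("&", "", masked, fixed = TRUE)
    ev <- system2(Sys.which("RNAeval"),
                  input = paste(sequence, masked, sep = "\n"), stdout = TRUE)
    e_target <- as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1",
                               ev[length(ev)]))
    min(1, exp((ens_energy - e_target) / kt))
  }
  list(mfe_energy = mfe_energy, mfe_structure = mfe_structure,
       ensemble_frequency = freq, ensemble_diversity = diversity)
}

# minimal working-directory sandbox (RNAfold -p drops dot-plot files)
withr_dir <- function(dir, body) {
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE)
  body()
}

#' Co-transcriptional folding-barrier score
#'
#' Heuristic: during transcription the 5' member of every kissing-loop
#' (pseudoknot) pair run is exposed long before its partner emerges; any
#' complementary decoy site transcribed in between can trap it. For each
#' pseudoknot run the score accumulates one term per decoy occurrence of the
#' run's reverse complement in the intervening sequence, weighted by
#' 1 / (1 + distance from the run); lower is better, 0 when the design has
#' no pseudoknots.
#'
#' @param spec a [target_spec()] (provides the pseudoknot layout)
#' @param sequence concrete RNA sequence of matching length
#' @return non-negative numeric score
#' @export
folding_barrier_score <- function(spec, sequence) {
  stopifnot(inherits(spec, "target_spec"))
  sequence <- gsub("&", "", sequence, fixed = TRUE)
  if (nchar(sequence) != spec$n) {
    stop("sequence length does not match target (", spec$n, " nt)")
  }
  pk <- spec$pairs[spec$pairs$layer > 0L, , drop = FALSE]
  if (nrow(pk) == 0L) return(0)
  pk <- pk[order(pk$i), , drop = FALSE]
  # split pseudoknot pairs into antiparallel runs
  run_id <- cumsum(c(TRUE, diff(pk$i) != 1L | diff(pk$j) != -1L))
  total <- 0
  for (rid in unique(run_id)) {
    run <- pk[run_id == rid, , drop = FALSE]
    i1 <- min(run$i); i2 <- max(run$i)
    j1 <- min(run$j)
    core <- substr(sequence, i1, i2)
    window_start <- i2 + 1L
    window_end <- j1 - 1L
    if (window_end - window_start + 1L < nchar(core)) next
    window <- substr(sequence, window_start, window_end)
    hits <- find_subsequence(window, reverse_complement(core))
    # exclude the true partner site if it protrudes into the window
    for (h in hits) {
      pos <- window_start + h          # 1-based global start of the decoy
      if (pos >= j1 - nchar(core) + 1L) next
      total <- total + 1 / (1 + (pos - i2))
    }
  }
  total
}
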