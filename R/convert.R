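#' @title Sequence conversion and analytics
#' @description Downstream utilities between sequence design and the bench:
#'   DNA template construction with a transcriptional promoter, GC content,
#'   IUPAC subsequence search and duplex (dimer) prediction.
#' @name convert_prepare
NULL

.PROMOTERS <- c(T7 = "TAATACGACTCACTATAG")

dna_reverse_complement <- function(seq) rna_to_dna_letters(reverse_complement(seq))

#' Convert an RNA sequence to a DNA template record
#'
#' Maps U to T and prepends a transcriptional promoter (by default the T7
#' consensus `TAATACGACTCACTATAG`). The promoter's 3'-terminal G is the +1
#' transcript position: when the RNA starts with G the G is shared rather
#' than duplicated; otherwise the full RNA is appended after the promoter and
#' a low-transcription-efficiency warning is recorded.
#'
#' @param rna RNA sequence (A/C/G/U)
#' @param promoter `"T7"`, a custom promoter sequence, or `""` for none
#' @return a `template_record`: `coding_dna`, `template_strand` (its reverse
#'   complement), `promoter_name`, `promoter_seq`, `transcript_start`
#'   (1-based position of the +1 nucleotide in `coding_dna`), `warnings`
#' @export
rna_to_dna <- function(rna, promoter = "T7") {
  if (!is.character(rna) || length(rna) != 1L || nchar(rna) == 0L) {
    stop("rna must be a non-empty string")
  }
  rna <- toupper(rna)
  bad <- setdiff(unique(chars(rna)), iupac_letters())
  if (length(bad) > 0L) {
    stop("invalid nucleotide code(s) in RNA: ", paste(bad, collapse = " "))
  }
  gene <- rna_to_dna_letters(rna)
  promoter_name <- if (promoter %in% names(.PROMOTERS)) promoter else
    if (nzchar(promoter)) "custom" else "none"
  pseq <- if (promoter %in% names(.PROMOTERS)) .PROMOTERS[[promoter]]
          else toupper(promoter)
  warnings <- character(0)
  if (nzchar(pseq)) {
    if (startsWith(gene, "G") && endsWith(pseq, "G")) {
      coding <- paste0(substr(pseq, 1L, nchar(pseq) - 1L), gene)
      transcript_start <- nchar(pseq)
    } else {
      coding <- paste0(pseq, gene)
      transcript_start <- nchar(pseq) + 1L
      warnings <- c(warnings, paste0(
        "transcript does not start with G at the promoter +1 position; ",
        "expect low transcription efficiency"))
    }
  } else {
    coding <- gene
    transcript_start <- 1L
  }
  structure(list(coding_dna = coding,
                 template_strand = dna_reverse_complement(coding),
                 promoter_name = promoter_name, promoter_seq = pseq,
                 transcript_start = transcript_start,
                 warnings = warnings),
            class = "template_record")
}

#' Transcript encoded by a template record
#'
#' @param record a `template_record`
#' @return the RNA produced downstream of the promoter (T to U mapping)
#' @export
transcribe <- function(record) {
  stopifnot(inherits(record, "template_record"))
  dna_to_rna_letters(substr(record$coding_dna, record$transcript_start,
                            nchar(record$coding_dna)))
}

#' @export
print.template_record <- function(x, ...) {
  cat("<template_record> ", nchar(x$coding_dna), " bp coding strand, promoter: ",
      x$promoter_name, "\n", sep = "")
  cat("  5'-", substr(x$coding_dna, 1, 60),
      if (nchar(x$coding_dna) > 60) "..." else "", "-3'\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' GC content
#'
#' @param seq nucleotide sequence
#' @return fraction of G and C bases, in `[0, 1]`
#' @export
gc_content <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("empty sequence")
  }
  ch <- chars(toupper(seq))
  sum(ch %in% c("G", "C")) / length(ch)
}

#' IUPAC subsequence search
#'
#' All positions (0-based, overlapping) where the sequence matches the query:
#' at every offset each query code's IUPAC class must contain the sequence
#' base.
#'
#' @param seq concrete nucleotide sequence
#' @param query IUPAC query (ambiguity codes allowed)
#' @return integer vector of 0-based match positions (empty when none)
#' @export
#' @examples
#' find_subsequence("GGAGG", "GG")   # 0, 3
find_subsequence <- function(seq, query) {
  seq <- toupper(seq); query <- toupper(query)
  n <- nchar(seq); m <- nchar(query)
  if (m == 0L || m > n) return(integer(0))
  sc <- chars(seq); qc <- chars(query)
  qsets <- lapply(qc, iupac_bases)
  sc[sc == "T"] <- "U"
  hits <- integer(0)
  for (p in 0:(n - m)) {
    ok <- TRUE
    for (k in seq_len(m)) {
      if (!sc[p + k] %in% qsets[[k]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

#' Predict the best dimer between two sequences
#'
#' Maximal antiparallel complementary run over all alignments of `seq1`
#' (5' to 3') against `seq2` (3' to 5'), scored +1 per Watson-Crick pair with
#' runs broken by mismatches. Ties are resolved deterministically: smallest
#' alignment offset, then smallest start.
#'
#' @param seq1,seq2 nucleotide sequences (RNA or DNA lettering)
#' @return list: `length` (longest complementary run), `start1` (1-based
#'   start in `seq1`), `start2` (1-based start in `seq2`, 5' to 3'
#'   numbering), `offset` (alignment offset), `score`
#' @export
dimer_prediction <- function(seq1, seq2) {
  if (nchar(seq1) == 0L || nchar(seq2) == 0L) stop("empty sequence")
  a <- chars(dna_to_rna_letters(toupper(seq1)))
  b <- chars(dna_to_rna_letters(toupper(seq2)))
  n1 <- length(a); n2 <- length(b)
  best <- list(length = 0L, start1 = NA_integer_, start2 = NA_integer_,
               offset = NA_integer_, score = 0L)
  # offset o: seq1 position i faces seq2 position (n2 - (i - o) + 1)
  for (o in (1L - n2):(n1 - 1L)) {
    run <- 0L; run_start <- NA_integer_
    lo <- max(1L, 1L + o); hi <- min(n1, n2 + o)
    if (lo > hi) next
    for (i in lo:hi) {
      j <- n2 - (i - o) + 1L
      if (iupac_can_pair(a[i], b[j])) {
        if (run == 0L) run_start <- i
        run <- run + 1L
        if (run > best$length) {
          best <- list(length = run, start1 = run_start,
                       start2 = n2 - (run_start + run - 1L - o) + 1L,
                       offset = o, score = run)
        }
      } else {
        run <- 0L
      }
    }
  }
  best
}
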