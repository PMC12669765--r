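#' @title Melting temperature and primer design
#' @description Nearest-neighbor duplex thermodynamics with the unified DNA
#'   parameter set (Allawi & SantaLucia 1998): enthalpy/entropy accumulation
#'   over dinucleotide stacks with terminal initiation terms and a symmetry
#'   correction, an entropic salt correction (0.368 (N-1) ln[monovalent
#'   equivalent]) with the von Ahsen divalent equivalence (+120 sqrt(Mg)),
#'   and the two-state Tm = dH / (dS + R ln CT/4). Primer design anchors the
#'   forward primer at the coding 5' end and the reverse primer at the 3' end
#'   and trims/extends each at its 3' terminus to the length whose Tm is
#'   nearest the target.
#' @name thermo
NULL

# unified NN table: dH kcal/mol, dS cal/(mol K)
.NN_UNIFIED <- list(
  "AA" = c(-7.9, -22.2), "TT" = c(-7.9, -22.2),
  "AT" = c(-7.2, -20.4),
  "TA" = c(-7.2, -21.3),
  "CA" = c(-8.5, -22.7), "TG" = c(-8.5, -22.7),
  "GT" = c(-8.4, -22.4), "AC" = c(-8.4, -22.4),
  "CT" = c(-7.8, -21.0), "AG" = c(-7.8, -21.0),
  "GA" = c(-8.2, -22.2), "TC" = c(-8.2, -22.2),
  "CG" = c(-10.6, -27.2),
  "GC" = c(-9.8, -24.4),
  "GG" = c(-8.0, -19.9), "CC" = c(-8.0, -19.9))
.NN_INIT_AT <- c(2.3, 4.1)
.NN_INIT_GC <- c(0.1, -2.8)
.NN_SYM <- c(0, -1.4)
.GAS_R <- 1.987          # cal/(mol K)

#' PCR / buffer conditions for thermodynamic calculations
#'
#' @param monovalent_mM monovalent cation concentration (Na+ equivalents), mM
#' @param divalent_mM divalent cation concentration (Mg2+), mM
#' @param oligo_nM total oligonucleotide concentration, nM
#' @param nn_set nearest-neighbor parameter set id (packaged:
#'   `"unified1998"`)
#' @return a `thermo_conditions` list
#' @export
thermo_conditions <- function(monovalent_mM = 50, divalent_mM = 0,
                              oligo_nM = 500, nn_set = "unified1998") {
  if (monovalent_mM < 0 || divalent_mM < 0 || oligo_nM < 0) {
    stop("concentrations must be >= 0")
  }
  if (!nn_set %in% "unified1998") {
    stop("unknown nearest-neighbor parameter set '", nn_set, "'")
  }
  structure(list(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
                 oligo_nM = oligo_nM, nn_set = nn_set),
            class = "thermo_conditions")
}

#' Nearest-neighbor melting temperature
#'
#' @param seq DNA sequence (>= 8 nt; U accepted and treated as T)
#' @param cond [thermo_conditions()]
#' @return melting temperature, degrees Celsius
#' @export
melting_temperature <- function(seq, cond = thermo_conditions()) {
  stopifnot(inherits(cond, "thermo_conditions"))
  seq <- chartr("Uu", "Tt", toupper(seq))
  seq <- toupper(seq)
  if (nchar(seq) < 8L) {
    stop("sequence too short for nearest-neighbor Tm (>= 8 nt required)")
  }
  ch <- chars(seq)
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stop("Tm calculation requires a concrete A/C/G/T sequence")
  }
  n <- length(ch)
  dH <- 0; dS <- 0
  for (k in seq_len(n - 1L)) {
    nn <- .NN_UNIFIED[[paste0(ch[k], ch[k + 1L])]]
    dH <- dH + nn[1]; dS <- dS + nn[2]
  }
  for (terminal in c(ch[1], ch[n])) {
    init <- if (terminal %in% c("A", "T")) .NN_INIT_AT else .NN_INIT_GC
    dH <- dH + init[1]; dS <- dS + init[2]
  }
  selfcomp <- identical(seq, dna_reverse_complement(seq))
  if (selfcomp) { dH <- dH + .NN_SYM[1]; dS <- dS + .NN_SYM[2] }
  # entropic salt correction with divalent equivalence
  mon <- cond$monovalent_mM + 120 * sqrt(max(cond$divalent_mM, 0))
  if (mon <= 0) stop("no cations: salt correction undefined")
  dS_corr <- dS + 0.368 * (n - 1L) * log(mon * 1e-3)
  ct <- cond$oligo_nM * 1e-9
  k_conc <- if (selfcomp) ct / 2 else ct / 4
  1000 * dH / (dS_corr + .GAS_R * log(k_conc)) - 273.15
}

#' Automatic end-anchored primer design
#'
#' The forward primer is a prefix of the coding strand, the reverse primer
#' the reverse complement of its suffix; each is extended or trimmed at its
#' 3' terminus to the length (within bounds) whose melting temperature is
#' nearest `target_tm`. Deterministic: ties go to the shorter primer.
#'
#' @param template a `template_record` (see [rna_to_dna()]) or a plain DNA
#'   sequence
#' @param target_tm target melting temperature, Celsius (default 69)
#' @param tolerance acceptable deviation from `target_tm`, Celsius
#' @param length_bounds allowed primer lengths (default 15-40 nt)
#' @param cond [thermo_conditions()]
#' @return a `primer_pair`: `forward`, `reverse`, `tm_forward`, `tm_reverse`,
#'   `target_tm`
#' @export
design_primers <- function(template, target_tm = 69, tolerance = 1.5,
                           length_bounds = c(15L, 40L),
                           cond = thermo_conditions()) {
  coding <- if (inherits(template, "template_record")) template$coding_dna
            else chartr("Uu", "Tt", toupper(template))
  n <- nchar(coding)
  lo <- length_bounds[1]; hi <- min(length_bounds[2], n)
  if (n < 2L * lo) {
    stop("template too short (", n, " nt) for two ", lo, "-nt primers")
  }
  pick <- function(candidates) {
    tms <- vapply(candidates, melting_temperature, numeric(1), cond = cond)
    best <- which.min(abs(tms - target_tm))   # ties: first = shortest
    list(seq = candidates[best], tm = tms[best])
  }
  fwd <- pick(vapply(lo:hi, function(l) substr(coding, 1L, l), character(1)))
  rev_anchor <- dna_reverse_complement(coding)
  rev <- pick(vapply(lo:hi, function(l) substr(rev_anchor, 1L, l), character(1)))
  worst <- max(abs(fwd$tm - target_tm), abs(rev$tm - target_tm))
  if (worst > tolerance) {
    stop(sprintf(paste0(
      "no primer length in %d-%d reaches %.1f C within %.1f C; best ",
      "achievable: forward %.2f C (%d nt), reverse %.2f C (%d nt)"),
      lo, hi, target_tm, tolerance, fwd$tm, nchar(fwd$seq),
      rev$tm, nchar(rev$seq)))
  }
  structure(list(forward = fwd$seq, reverse = rev$seq,
                 tm_forward = fwd$tm, tm_reverse = rev$tm,
                 target_tm = target_tm, conditions = cond),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("<primer_pair> target Tm ", sprintf("%.1f", x$target_tm), " C\n",
      "  forward: 5'-", x$forward, "-3'  (", nchar(x$forward), " nt, Tm ",
      sprintf("%.2f", x$tm_forward), " C)\n",
      "  reverse: 5'-", x$reverse, "-3'  (", nchar(x$reverse), " nt, Tm ",
      sprintf("%.2f", x$tm_reverse), " C)\n", sep = "")
  invisible(x)
}
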