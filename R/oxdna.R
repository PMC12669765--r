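#' @title oxDNA file input/output
#' @description Conformations are serialized to the oxDNA new-topology dialect
#'   (5' to 3' strand records) plus the standard configuration format.
#'   Positions are stored in oxDNA simulation units (1 unit = 0.8518 nm);
#'   the package works in nm internally and converts on write/read.
#'   Topology: line 1 is `<nucleotides> <strands> 5->3`, then one line per
#'   strand: `<sequence> type=RNA circular=false`. Configuration: three
#'   header lines (`t = 0`, `b = <box>`, `E = 0 0 0`) then one line per
#'   nucleotide with 15 numbers: position, base vector, normal vector,
#'   velocity and angular velocity (zeroes).
#' @name oxdna
NULL

.OXDNA_UNIT_NM <- 0.8518

#' Write a conformation to oxDNA topology + configuration files
#'
#' @param conf an `origami_conformation`
#' @param topology_path,conf_path output paths
#' @return invisibly, the two paths
#' @export
write_oxdna <- function(conf, topology_path, conf_path) {
  stopifnot(inherits(conf, "origami_conformation"))
  n <- nrow(conf$poses)
  topo <- c(paste(n, length(conf$strand_nt), "5->3"),
            paste0(conf$sequences, " type=RNA circular=false"))
  writeLines(topo, topology_path)

  u <- .OXDNA_UNIT_NM
  box <- conf$box / u
  lines <- c(
    "t = 0",
    paste("b =", sprintf("%.8f", box[1]), sprintf("%.8f", box[2]),
          sprintf("%.8f", box[3])),
    "E = 0 0 0")
  if (n > 0L) {
    M <- cbind(conf$poses[, 1:3, drop = FALSE] / u,
               conf$poses[, 4:9, drop = FALSE],
               matrix(0, n, 6))
    lines <- c(lines, apply(M, 1L, function(r) {
      paste(sprintf("%.8f", r), collapse = " ")
    }))
  }
  writeLines(lines, conf_path)
  invisible(c(topology_path, conf_path))
}

#' Read oxDNA topology + configuration files
#'
#' @param topology_path,conf_path input paths
#' @return an `origami_conformation` (pair map empty: pairing is not part of
#'   the oxDNA file contract)
#' @export
read_oxdna <- function(topology_path, conf_path) {
  topo <- readLines(topology_path)
  if (length(topo) < 1L) stop("malformed topology file: empty")
  hdr <- strsplit(trimws(topo[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || is.na(suppressWarnings(as.integer(hdr[1])))) {
    stop("malformed topology file at line 1: expected '<n> <strands> 5->3'")
  }
  n <- as.integer(hdr[1]); ns <- as.integer(hdr[2])
  if (length(topo) < 1L + ns) {
    stop("malformed topology file: ", ns, " strand records expected, ",
         length(topo) - 1L, " found")
  }
  seqs <- vapply(topo[1L + seq_len(ns)], function(l) {
    strsplit(trimws(l), "\\s+")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  if (sum(nchar(seqs)) != n) {
    stop("malformed topology file: strand lengths sum to ", sum(nchar(seqs)),
         ", header says ", n)
  }
  cf <- readLines(conf_path)
  if (length(cf) < 3L + n) {
    stop("malformed configuration file: ", 3L + n, " lines expected, ",
         length(cf), " found")
  }
  u <- .OXDNA_UNIT_NM
  box <- as.numeric(strsplit(trimws(sub("^b\\s*=", "", cf[2])), "\\s+")[[1]]) * u
  poses <- matrix(NA_real_, n, 9)
  for (k in seq_len(n)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(cf[3L + k]), "\\s+")[[1]]))
    if (length(vals) < 9L || anyNA(vals[1:9])) {
      stop("malformed configuration file at line ", 3L + k)
    }
    poses[k, ] <- c(vals[1:3] * u, vals[4:9])
  }
  structure(list(poses = poses, strand_nt = nchar(seqs), sequences = seqs,
                 pairs = data.frame(i = integer(0), j = integer(0),
                                    layer = integer(0), wobble = logical(0)),
                 box = box, params = helix_params()),
            class = "origami_conformation")
}

.OXRNA_DEFAULTS <- list(
  relax = c(
    sim_type = "MD", backend = "CPU", interaction_type = "RNA2",
    steps = "1e6", dt = "0.003", T = "37C", salt_concentration = "1.0",
    thermostat = "bussi", bussi_tau = "1000", verlet_skin = "0.2",
    max_backbone_force = "5", max_backbone_force_far = "10",
    refresh_vel = "1", restart_step_counter = "1",
    print_energy_every = "1e4", print_conf_interval = "1e5"),
  production = c(
    sim_type = "MD", backend = "CPU", interaction_type = "RNA2",
    steps = "1e8", dt = "0.003", T = "37C", salt_concentration = "1.0",
    thermostat = "bussi", bussi_tau = "1000", verlet_skin = "0.2",
    refresh_vel = "1", restart_step_counter = "1",
    print_energy_every = "1e4", print_conf_interval = "1e5"))

#' Emit an oxRNA simulation input bundle
#'
#' Writes the topology and configuration files (via [write_oxdna()]) plus a
#' simulation parameter file with the packaged per-protocol defaults; any
#' defaults can be overridden and the overrides appear verbatim. No
#' simulation is executed.
#'
#' @param conf an `origami_conformation`
#' @param protocol `"relax"` or `"production"`
#' @param out_dir output directory (created if needed)
#' @param overrides named character vector/list of parameter overrides
#' @return character vector of the three emitted paths (topology,
#'   configuration, input file)
#' @export
oxrna_setup <- function(conf, protocol = c("relax", "production"),
                        out_dir = ".", overrides = c()) {
  protocol <- match.arg(protocol)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  topo <- file.path(out_dir, "origami.top")
  dat <- file.path(out_dir, "origami.dat")
  inp <- file.path(out_dir, paste0("input_", protocol))
  write_oxdna(conf, topo, dat)
  pars <- .OXRNA_DEFAULTS[[protocol]]
  ov <- unlist(overrides)
  if (length(ov) > 0L) pars[names(ov)] <- ov
  lines <- c(
    paste0("topology = ", basename(topo)),
    paste0("conf_file = ", basename(dat)),
    paste0("trajectory_file = trajectory_", protocol, ".dat"),
    paste0("lastconf_file = last_conf_", protocol, ".dat"),
    "energy_file = energy.dat",
    paste0(names(pars), " = ", pars))
  writeLines(lines, inp)
  invisible(c(topo, dat, inp))
}
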