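#' @title End-to-end design pipeline and test fixtures
#' @description `run_pipeline()` chains the four design stages -- Design
#'   (blueprint + target), Generate (sequence), Convert (DNA template) and
#'   Prepare (primers + oxRNA input files) -- over a packaged demo or a
#'   user origami, writing every artifact plus a provenance manifest.
#'   All randomness flows from the single configured seed, so a repeated run
#'   is byte-identical.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param design a demo name (`"filament_tile"`, `"rect_10h_3x"`,
#'   `"droplet_y_motif"`) or an `origami` object
#' @param out_dir output directory
#' @param seed integer seed recorded in all outputs
#' @param oracle use the ViennaRNA folding oracle during sequence design and
#'   report folding metrics (slow for large designs; default off)
#' @param thermo [thermo_conditions()] for primer design
#' @param promoter promoter for the DNA template (default `"T7"`)
#' @param target_tm primer target melting temperature, Celsius
#' @param tm_tolerance acceptable primer deviation from `target_tm`, Celsius
#' @param max_iterations sequence-design mutation budget
#' @param verbose print stage progress
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(design, out_dir = tempfile("origami"), seed = 1L,
                            oracle = FALSE, thermo = thermo_conditions(),
                            promoter = "T7", target_tm = 69,
                            tm_tolerance = 1.5,
                            max_iterations = 200L, verbose = FALSE) {
  if (is.character(design) && !design %in% .DEMOS) {
    stop("unknown demo '", design, "'; available: ",
         paste(.DEMOS, collapse = ", "))
  }
  if (!is.character(design) && !inherits(design, "origami")) {
    stop("design must be a demo name or an origami object")
  }
  structure(list(design = design, out_dir = out_dir, seed = as.integer(seed),
                 oracle = oracle, thermo = thermo, promoter = promoter,
                 target_tm = target_tm, tm_tolerance = tm_tolerance,
                 max_iterations = as.integer(max_iterations),
                 verbose = verbose),
            class = "pipeline_config")
}

stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full Design -> Generate -> Convert -> Prepare pipeline
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the main objects (`blueprint`, `target`,
#'   `design`, `template`, `primers`, `conformation`) and `files` (paths of
#'   all written artifacts)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  name <- if (is.character(config$design)) config$design else "custom"
  v <- config$verbose

  ori <- stage("design", v, {
    if (is.character(config$design)) demo_design(config$design)
    else config$design
  })
  bp <- stage("design", v, assemble(ori))
  write_blueprint(bp, out("blueprint.txt"))
  tgt <- stage("design", v, to_target(bp, name = name))
  write_target(tgt, out("target.txt"))

  res <- stage("generate", v, design_sequence(
    tgt, seed = config$seed, max_iterations = config$max_iterations,
    oracle = if (config$oracle) rnafold_oracle() else NULL))
  write_fasta(list(list(name = paste0(name, " seed=", config$seed),
                        sequence = res$sequence,
                        structure = tgt$structure)),
              out("sequence.fasta"))
  barrier <- folding_barrier_score(tgt, res$sequence)
  metrics <- if (config$oracle) {
    stage("generate", v, folding_metrics(
      gsub("&", "", res$sequence, fixed = TRUE), tgt$structure))
  }

  rna <- gsub("&", "", res$sequence, fixed = TRUE)
  tpl <- stage("convert", v, rna_to_dna(rna, config$promoter))
  write_fasta(list(
    list(name = paste0(name, " coding strand (", tpl$promoter_name,
                       " promoter)"), sequence = tpl$coding_dna),
    list(name = paste0(name, " template strand"),
         sequence = tpl$template_strand)),
    out("template.fasta"))

  primers <- stage("prepare", v, design_primers(
    tpl, target_tm = config$target_tm, tolerance = config$tm_tolerance,
    cond = config$thermo))
  writeLines(c(
    paste0("# primer report: ", name, " (seed ", config$seed, ")"),
    sprintf("target_tm_C\t%.2f", primers$target_tm),
    sprintf("forward\t%s\t%d nt\t%.2f C", primers$forward,
            nchar(primers$forward), primers$tm_forward),
    sprintf("reverse\t%s\t%d nt\t%.2f C", primers$reverse,
            nchar(primers$reverse), primers$tm_reverse)),
    out("primers.txt"))

  conf <- stage("prepare", v, build_conformation(bp, sequence = rna))
  ox <- oxrna_setup(conf, "relax", config$out_dir)

  files <- c(out("blueprint.txt"), out("target.txt"), out("sequence.fasta"),
             out("template.fasta"), out("primers.txt"), ox)
  manifest <- list(
    package = "origamir",
    version = tryCatch(as.character(utils::packageVersion("origamir")),
                       error = function(e) "dev"),
    design = name, seed = config$seed,
    n_nt = bp$n_nt, n_strands = length(bp$strands),
    design_iterations = res$iterations,
    repeat_score = res$repeat_score,
    folding_barrier_score = barrier,
    folding_metrics = metrics,
    promoter = config$promoter, target_tm = config$target_tm,
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(blueprint = bp, target = tgt, design = res, template = tpl,
                 primers = primers, conformation = conf,
                 manifest = manifest,
                 files = c(files, out("manifest.json"))))
}

#' Seed-deterministic random test fixture
#'
#' Builds a small randomized origami together with closed-form expected
#' totals (nucleotides, pairs, strand count) computed from the motif
#' inventory arithmetic, independently of the assembly walk.
#'
#' @param seed RNG seed
#' @param size one of `"tiny"` (2 helices, no kissing loops), `"small"`
#'   (2-3 helices, up to 1 kissing-loop column), `"medium"` (3-4 helices, up
#'   to 2 columns, possibly an aptamer cap)
#' @return list with `origami` and `expected` (`n_nt`, `n_pairs`,
#'   `n_strands`)
#' @export
make_fixture <- function(seed = 1L, size = c("tiny", "small", "medium")) {
  size <- match.arg(size)
  with_seed(seed, function() {
    n <- switch(size, tiny = 2L, small = sample(2:3, 1L),
                medium = sample(3:4, 1L))
    k <- switch(size, tiny = 0L, small = sample(0:1, 1L),
                medium = sample(0:2, 1L))
    L <- sample(5:9, 1L)
    d_abs <- pmin(sample(2:4, n - 1L, replace = TRUE), L)
    d <- d_abs * rep_len(c(-1L, 1L), n - 1L)
    apt <- size == "medium" && sample(c(TRUE, FALSE), 1L)
    ins <- if (apt) {
      list(list(motif = aptamer("Broccoli"), row = sample(n, 1L) - 1L,
                side = "east"))
    } else list()
    ori <- make_simple_origami(n, dovetails = d, kl_columns = k,
                               stem_length = L, insertions = ins)

    # closed-form totals, mirroring the generator's allocation arithmetic
    dt_w <- function(x) max(abs(x), 2L) + 4L
    pad <- rep(0L, n)
    if (n > 2L) {
      pad[1] <- dt_w(d[2]); pad[n] <- dt_w(d[n - 2L])
    }
    stem_bp <- sum((k + 1L) * (2L * L + pad)) + 10L * k
    dt_nt <- (k + 1L) * sum(2L * d_abs + 8L)
    dt_pairs <- (k + 1L) * sum(d_abs + 4L)
    n_kl <- k * (n - 1L)
    n_caps <- 2L * n - length(ins)
    apt_nt <- if (apt) 49L else 0L
    apt_pairs <- if (apt) 13L else 0L
    expected <- list(
      n_nt = 2L * stem_bp + dt_nt + 14L * n_kl + 4L * n_caps + apt_nt,
      n_pairs = stem_bp + dt_pairs + 6L * n_kl + apt_pairs,
      n_strands = 1L)
    list(origami = ori, expected = expected)
  })
}
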