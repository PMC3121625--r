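## Report assembly and the command-line front end.
##
## run_report() ties the analysis stages into one bundle of TSV/JSON/BED
## outputs; mito_cli() exposes the stages as subcommands.  Outputs carry no
## timestamps, so re-running with identical inputs yields byte-identical
## files; run metadata (thresholds in force) goes to the manifest and the
## stderr log.

#' Assemble a run configuration
#'
#' @param input Path to a GenBank file (or `NULL` when simulating).
#' @param out_dir Output directory (created if missing).
#' @param main_strand_override `NULL`, `"main"` or `"opposite"`.
#' @param window_left,window_right Profile window extent.
#' @param smooth_span Origin-inference smoothing span.
#' @param trend_threshold Threshold mode for [fit_trend()].
#' @param code_id Genetic code (see [genetic_code()]).
#' @param anticodon_file Optional TSV of tRNA anticodons.
#' @param grade_thresholds,call_threshold Code-inference thresholds.
#' @param seed Seed for any simulation involved.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, out_dir = "mitoskew-out",
                       main_strand_override = NULL,
                       window_left = 149L, window_right = 150L,
                       smooth_span = 300L, trend_threshold = "slope",
                       code_id = "rhabdopleura", anticodon_file = NULL,
                       grade_thresholds = c(0.9, 0.7, 0.5),
                       call_threshold = 0.45, seed = 1L) {
  stopifnot(call_threshold >= 0, call_threshold <= 1,
            all(grade_thresholds >= 0), all(grade_thresholds <= 1),
            window_left + window_right + 1L > 0L)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a flat key=value file
#'
#' Unknown keys raise an error; numeric-looking values are coerced.
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  numeric_keys <- c("window_left", "window_right", "smooth_span",
                    "call_threshold", "seed")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- stats::setNames(Map(function(k, x) {
    v <- x[2]
    if (k %in% numeric_keys && grepl("^-?[0-9.]+$", v)) as.numeric(v) else v
  }, keys, kv), keys)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) stop("unknown config key(s): ",
                             paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

log_msg <- function(verbose, ...) {
  if (verbose) message("[mitoskew] ", sprintf(...))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_uas <- function(genome, uas, base) {
  regs <- uas$regions
  n <- genome_length(genome)
  bed <- data.frame(chrom = genome$id,
                    chromStart = regs$start,
                    chromEnd = pmin(regs$end, n),
                    name = paste0(regs$upstream, "|", regs$downstream),
                    score = regs$length)
  writeLines(apply(bed, 1, paste, collapse = "\t"), paste0(base, ".bed"))
  write_tsv(cbind(genome = genome$id, regs,
                  fraction = round(uas$fraction, 5)), paste0(base, ".tsv"))
}

#' Run the full analysis report on one genome
#'
#' Produces the composition table, UAS census (TSV + BED), homopolymer-run
#' census, (G+T)/(A+C) profile with shading flags, origin inference, codon
#' usage, pairing report with deviation count, and a manifest recording
#' every threshold in force.  Any stage failure leaves the already-written
#' outputs in place, records the failure in the manifest, and re-raises.
#'
#' @param config A [run_config()].
#' @param genome Optional [annotated_genome()] (otherwise read from
#'   `config$input`).
#' @param verbose Log stages to stderr.
#' @return Invisibly, a named list of output paths.
#' @export
run_report <- function(config, genome = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- list()
  manifest <- list(package = "mitoskew",
                   thresholds = list(
                     window_left = config$window_left,
                     window_right = config$window_right,
                     smooth_span = config$smooth_span,
                     trend_threshold = config$trend_threshold,
                     grade_thresholds = config$grade_thresholds,
                     call_threshold = config$call_threshold),
                   code_id = config$code_id, status = "failed")
  finish <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  on.exit(finish())
  if (is.null(genome)) {
    if (is.null(config$input)) stop("run_report needs a genome or an input")
    log_msg(verbose, "reading %s", config$input)
    genome <- read_genbank(config$input)
  }
  genome <- orient_main(genome, config$main_strand_override)
  manifest$genome <- list(id = genome$id, length = genome_length(genome))
  p <- function(name) file.path(config$out_dir, name)

  log_msg(verbose, "composition")
  outs$composition <- write_tsv(composition_table(genome),
                                p("composition.tsv"))
  log_msg(verbose, "UAS census")
  uas <- unassigned_regions(genome)
  write_uas(genome, uas, p("uas"))
  outs$uas <- p("uas.tsv")
  log_msg(verbose, "homopolymer runs")
  runs <- homopolymer_runs(genome$sequence, "T", circular = genome$circular)
  outs$runs <- write_tsv(data.frame(base = runs$base,
                                    length = names(runs$counts),
                                    count = runs$counts), p("runs.tsv"))
  log_msg(verbose, "ratio profile (window %d+%d+1)", config$window_left,
          config$window_right)
  prof <- ratio_profile(genome, config$window_left, config$window_right)
  trend <- fit_trend(prof, config$trend_threshold)
  outs$profile <- write_tsv(
    data.frame(position = seq_len(prof$n) - 1L,
               ratio = round(prof$values, 6),
               shaded = trend$shading_mask), p("profile.tsv"))
  ori <- infer_origins(prof, genome, config$smooth_span)
  jsonlite::write_json(
    list(oriL = ori$oriL, oriL_genes = ori$oriL_genes,
         oriH = ori$oriH, oriH_genes = ori$oriH_genes,
         smooth_span = ori$smooth_span,
         trend = list(slope = trend$slope, intercept = trend$intercept,
                      threshold = trend$threshold,
                      mode = trend$threshold_mode)),
    p("origins.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outs$origins <- p("origins.json")

  if (length(features_of_kind(genome, "CDS")) > 0L) {
    log_msg(verbose, "codon usage under code %s", config$code_id)
    code <- genetic_code(config$code_id)
    usage <- codon_usage(genome, code)
    anticodons <- if (!is.null(config$anticodon_file)) {
      read_anticodons(config$anticodon_file)
    } else NULL
    outs$codon_usage <- write_codon_usage(usage, p("codon_usage.tsv"),
                                          anticodons)
    aa <- aa_composition(usage)
    outs$aa_composition <- write_tsv(
      data.frame(aa = aa_three_letter(names(aa)),
                 frequency = round(unname(aa), 6),
                 strandedness = vapply(names(aa),
                                       classify_codon_strandedness,
                                       character(1), code = code)),
      p("aa_composition.tsv"))
    if (!is.null(anticodons)) {
      log_msg(verbose, "pairing classification")
      pairing <- classify_pairing(anticodons, code, usage)
      fam <- pairing$families
      fam$deviations_total <- pairing$deviations
      outs$pairing <- write_tsv(fam, p("pairing.tsv"))
      outs$adaptation <- write_tsv(adaptation_test(anticodons, usage),
                                   p("adaptation.tsv"))
    }
  }
  manifest$status <- "ok"
  manifest$outputs <- names(outs)
  log_msg(verbose, "done: %d outputs in %s", length(outs), config$out_dir)
  invisible(outs)
}

#' Command-line entry point
#'
#' Subcommands: `compose`, `profile`, `codons`, `pairing`, `infer-code`,
#' `atlas`, `simulate`, `report`.  Run `mito_cli(c("<cmd>", "--help"))` for
#' per-command options.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Exit status 0 invisibly on success; errors propagate.
#' @export
mito_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: mitoskew <compose|profile|codons|pairing|infer-code|atlas|simulate|report> [options]"
  if (length(args) == 0L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  common <- list(
    optparse::make_option("--out", type = "character",
                          default = "mitoskew-out"),
    optparse::make_option("--code", type = "character",
                          default = "rhabdopleura"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--quiet", action = "store_true", default = FALSE))
  parse <- function(extra = list()) {
    optparse::parse_args(
      optparse::OptionParser(option_list = c(common, extra)),
      args = rest, positional_arguments = TRUE)
  }
  read_input <- function(opt) {
    if (length(opt$args) < 1L) stop("missing input GenBank file")
    read_genbank(opt$args[1])
  }
  switch(cmd,
    compose = {
      opt <- parse()
      g <- read_input(opt)
      dir.create(opt$options$out, showWarnings = FALSE, recursive = TRUE)
      write_tsv(composition_table(g),
                file.path(opt$options$out, "composition.tsv"))
      uas <- unassigned_regions(g)
      write_uas(g, uas, file.path(opt$options$out, "uas"))
    },
    profile = {
      opt <- parse(list(
        optparse::make_option("--window-left", type = "integer",
                              default = 149L),
        optparse::make_option("--window-right", type = "integer",
                              default = 150L),
        optparse::make_option("--smooth-span", type = "integer",
                              default = 300L),
        optparse::make_option("--threshold", type = "character",
                              default = "slope")))
      g <- read_input(opt)
      cfg <- run_config(out_dir = opt$options$out,
                        window_left = opt$options$window_left,
                        window_right = opt$options$window_right,
                        smooth_span = opt$options$smooth_span,
                        trend_threshold = opt$options$threshold)
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      prof <- ratio_profile(g, cfg$window_left, cfg$window_right)
      trend <- fit_trend(prof, cfg$trend_threshold)
      write_tsv(data.frame(position = seq_len(prof$n) - 1L,
                           ratio = round(prof$values, 6),
                           shaded = trend$shading_mask),
                file.path(cfg$out_dir, "profile.tsv"))
      ori <- infer_origins(prof, g, cfg$smooth_span)
      jsonlite::write_json(
        list(oriL = ori$oriL, oriL_genes = ori$oriL_genes,
             oriH = ori$oriH, oriH_genes = ori$oriH_genes),
        file.path(cfg$out_dir, "origins.json"), auto_unbox = TRUE,
        digits = NA)
    },
    codons = {
      opt <- parse()
      g <- read_input(opt)
      dir.create(opt$options$out, showWarnings = FALSE, recursive = TRUE)
      write_codon_usage(codon_usage(g, genetic_code(opt$options$code)),
                        file.path(opt$options$out, "codon_usage.tsv"))
    },
    pairing = {
      opt <- parse(list(
        optparse::make_option("--anticodons", type = "character")))
      g <- read_input(opt)
      if (is.null(opt$options$anticodons)) stop("--anticodons is required")
      code <- genetic_code(opt$options$code)
      usage <- codon_usage(g, code)
      anticodons <- read_anticodons(opt$options$anticodons)
      pairing <- classify_pairing(anticodons, code, usage)
      dir.create(opt$options$out, showWarnings = FALSE, recursive = TRUE)
      fam <- pairing$families
      fam$deviations_total <- pairing$deviations
      write_tsv(fam, file.path(opt$options$out, "pairing.tsv"))
      message("deviations from highest versatility: ", pairing$deviations)
    },
    `infer-code` = {
      opt <- parse(list(
        optparse::make_option("--alignments", type = "character"),
        optparse::make_option("--call-threshold", type = "double",
                              default = 0.45)))
      g <- read_input(opt)
      if (is.null(opt$options$alignments)) {
        stop("--alignments (directory of per-gene aligned FASTA) is required")
      }
      files <- list.files(opt$options$alignments, "\\.(fa|fasta|afa)$",
                          full.names = TRUE)
      alns <- lapply(files, read_alignment_fasta)
      names(alns) <- vapply(alns, `[[`, character(1), "gene")
      inf <- infer_code(g, alns,
                        call_threshold = opt$options$call_threshold,
                        base_code = genetic_code(opt$options$code))
      dir.create(opt$options$out, showWarnings = FALSE, recursive = TRUE)
      write_tsv(inf$calls, file.path(opt$options$out, "code_calls.tsv"))
    },
    atlas = {
      opt <- parse(list(
        optparse::make_option("--groups", type = "character",
                              default = NULL)))
      if (length(opt$args) < 1L) stop("need at least one GenBank file")
      genomes <- lapply(opt$args, read_genbank)
      grouping <- if (!is.null(opt$options$groups)) {
        gdf <- utils::read.delim(opt$options$groups,
                                 stringsAsFactors = FALSE)
        ids <- vapply(genomes, `[[`, character(1), "id")
        gdf$group[match(ids, gdf$id)]
      } else NULL
      atlas <- skew_atlas(genomes, grouping)
      dir.create(opt$options$out, showWarnings = FALSE, recursive = TRUE)
      write_tsv(atlas$points, file.path(opt$options$out,
                                        "atlas_points.tsv"))
      jsonlite::write_json(
        lapply(atlas$ellipses, function(e) {
          list(group = e$group, n = e$n, mean = unname(e$mean),
               eigenvalues = e$eigenvalues,
               major_axis = e$eigenvectors[, 1],
               min = unname(e$min), max = unname(e$max),
               degenerate = e$degenerate)
        }),
        file.path(opt$options$out, "atlas_ellipses.json"),
        auto_unbox = TRUE, digits = NA)
    },
    simulate = {
      opt <- parse(list(
        optparse::make_option("--preset", type = "character",
                              default = "rhabdopleura")))
      params <- sim_params(preset = opt$options$preset,
                           seed = opt$options$seed)
      sim <- generate_genome(params)
      dir.create(opt$options$out, showWarnings = FALSE, recursive = TRUE)
      write_genbank(sim$genome,
                    file.path(opt$options$out, "synthetic.gb"))
      truth <- sim$truth
      truth$realized_counts <- unclass(truth$realized_counts)
      jsonlite::write_json(truth, file.path(opt$options$out, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    report = {
      opt <- parse(list(
        optparse::make_option("--anticodons", type = "character",
                              default = NULL),
        optparse::make_option("--config", type = "character",
                              default = NULL)))
      cfg <- if (!is.null(opt$options$config)) {
        read_run_config(opt$options$config)
      } else {
        run_config(input = if (length(opt$args)) opt$args[1] else NULL,
                   out_dir = opt$options$out,
                   code_id = opt$options$code,
                   anticodon_file = opt$options$anticodons,
                   seed = opt$options$seed)
      }
      run_report(cfg, verbose = !opt$options$quiet)
    },
    stop("unknown subcommand '", cmd, "'\n", usage)
  )
  invisible(0L)
}
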