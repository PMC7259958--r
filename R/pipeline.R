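#' Assemble and validate a pipeline run configuration
#'
#' Thresholds default to the values the rolling-circle design dictates: a
#' recomputed posterior error probability of at most 1e-7 per assayed call, at
#' least two tandem repeats per fragment, a strict site-frequency ceiling of
#' 1% separating transcript errors from genetic variants, and a period-search
#' identity acceptance of 0.85. Every default can be overridden.
#'
#' @param sim optional `sim_config`; when present the pipeline simulates its
#'   input instead of reading files.
#' @param fastq_path,fasta_path,gff_path input files for a file-based run.
#' @param sam_path optional externally produced alignments of the duplicated
#'   consensus sequences; when given the SAM import path replaces the built-in
#'   mapper.
#' @param code_table NCBI translation-table id (required for file-based runs).
#' @param q_threshold,min_repeats,max_frequency,min_identity,min_period,trim
#'   stage thresholds (see the stage functions).
#' @param window,window_step,window_min_assayed sliding-window track settings.
#' @param paralog_filter apply the ncRNA paralog filter.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, fastq_path = NULL, fasta_path = NULL,
                       gff_path = NULL, sam_path = NULL, code_table = NULL,
                       q_threshold = 1e-7, min_repeats = 2L,
                       max_frequency = 0.01, min_identity = 0.85,
                       min_period = 25L, trim = 4L,
                       window = 10000L, window_step = 100L,
                       window_min_assayed = 1e4, paralog_filter = TRUE) {
  cfg <- list(sim = sim, fastq_path = fastq_path, fasta_path = fasta_path,
              gff_path = gff_path, sam_path = sam_path,
              code_table = code_table, q_threshold = q_threshold,
              min_repeats = as.integer(min_repeats),
              max_frequency = max_frequency, min_identity = min_identity,
              min_period = as.integer(min_period), trim = as.integer(trim),
              window = as.integer(window), window_step = as.integer(window_step),
              window_min_assayed = window_min_assayed,
              paralog_filter = paralog_filter)
  if (!(q_threshold > 0 && q_threshold < 1)) stop("q_threshold must be in (0,1)")
  if (!(max_frequency > 0 && max_frequency <= 1)) stop("max_frequency must be in (0,1]")
  if (!(min_identity > 0 && min_identity <= 1)) stop("min_identity must be in (0,1]")
  if (cfg$min_repeats < 2) stop("min_repeats below 2 cannot separate RT errors")
  if (is.null(sim) && (is.null(fastq_path) || is.null(fasta_path) ||
                       is.null(gff_path) || is.null(code_table))) {
    stop("file-based runs need fastq_path, fasta_path, gff_path and code_table")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full transcript-error pipeline
#'
#' Chains simulation (or file input), period detection and consensus
#' building, duplicated-consensus mapping, pileup accumulation, error calling
#' and all downstream statistics, with complete filter accounting. When
#' `outdir` is given, stage outputs are written (error-call TSV and VCF,
#' spectrum and rate JSON/TSV, per-gene enrichment table, distance series,
#' window track as bedGraph, and a JSON manifest with the configuration and
#' filter counts).
#'
#' @param config `run_config`.
#' @param outdir optional output directory.
#' @return list with all stage objects (`genome`, `reads` summary,
#'   `consensus`, `fragments`, `pileup`, `errors`, `rates`, `spectrum`,
#'   `indels`, `effects`, `enrichment`, `nonsense`, `regression`, `track`,
#'   `filter_counts`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (!is.null(config$sim)) {
    ref <- simulate_reference(config$sim)
    genome <- ref$genome
    rd <- simulate_reads(config$sim, genome, ref$expression)
    reads <- rd$reads
    truth <- rd$truth
  } else {
    genome <- load_reference(config$fasta_path, config$gff_path,
                             config$code_table)
    reads <- read_rolling_reads(config$fastq_path)
  }
  cs <- consensus_set(reads, min_period = config$min_period,
                      min_identity = config$min_identity,
                      min_repeats = config$min_repeats)
  frags <- if (is.null(config$sam_path)) {
    map_fragments(cs, genome, trim = config$trim)
  } else {
    import_alignments(config$sam_path, cs, genome, trim = config$trim)
  }
  pile <- accumulate_pileup(frags, genome, q_threshold = config$q_threshold)
  ec <- call_errors(pile, genome, max_frequency = config$max_frequency,
                    paralog_filter = config$paralog_filter)
  ec <- annotate_effects(ec, genome)

  rates <- list(all = error_rate(ec, "all"),
                cds = error_rate(ec, "cds", genome),
                ncRNA = error_rate(ec, "ncRNA", genome),
                other = error_rate(ec, "other", genome))
  spectrum <- substitution_spectrum(ec)
  indels <- call_indel_errors(ec, max_frequency = config$max_frequency)
  effects <- tryCatch({
    usage <- codon_usage(genome)
    list(observed = observed_effect_percentages(ec),
         expected = expected_effect_percentages(spectrum, usage,
                                                genome$code_table_id))
  }, error = function(e) list(observed = NULL, expected = NULL,
                              note = conditionMessage(e)))
  enrichment <- tryCatch(gene_enrichment(ec, genome),
                         error = function(e) NULL)
  nonsense <- tryCatch(nonsense_distance_series(ec, genome),
                       error = function(e) NULL)
  regression <- tryCatch(weighted_regression(nonsense$points),
                         error = function(e) NULL)
  track <- window_error_track(ec, genome, window = config$window,
                              step = config$window_step,
                              min_assayed = config$window_min_assayed)

  filter_counts <- c(cs$counts, frags$counts[-1], ec$counts)
  out <- list(genome = genome, n_reads = nrow(reads), consensus = cs,
              fragments = frags, pileup = pile, errors = ec, rates = rates,
              spectrum = spectrum, indels = indels, effects = effects,
              enrichment = enrichment, nonsense = nonsense,
              regression = regression, track = track,
              filter_counts = filter_counts, truth = truth)
  if (!is.null(outdir)) .write_pipeline_outputs(out, config, outdir)
  out
}

.write_pipeline_outputs <- function(out, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_error_calls(out$errors, file.path(outdir, "error_calls.tsv"),
                    file.path(outdir, "error_calls.vcf"))
  utils::write.table(as.data.frame(out$spectrum),
                     file.path(outdir, "spectrum.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(out$enrichment)) {
    utils::write.table(out$enrichment, file.path(outdir, "gene_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$nonsense)) {
    utils::write.table(out$nonsense$points,
                       file.path(outdir, "nonsense_distance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  bg <- out$track[!is.na(out$track$rate), , drop = FALSE]
  writeLines(c("track type=bedGraph name=transcript_error_rate",
               sprintf("%s\t%d\t%d\t%.3g", bg$replicon, bg$start - 1L, bg$end,
                       bg$rate)),
             file.path(outdir, "error_rate_track.bedgraph"))
  summary <- list(
    rates = lapply(out$rates, function(r) r[c("rate", "errors", "assayed")]),
    indel = out$indels[c("rate", "ratio_to_substitution")],
    effects = if (!is.null(out$effects$observed))
      list(observed = as.list(out$effects$observed$percentages),
           expected = as.list(out$effects$expected$percentages)) else NULL,
    regression = out$regression,
    filter_counts = as.list(out$filter_counts))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest <- list(
    package = "circlecall",
    version = as.character(utils::packageVersion("circlecall")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[!vapply(config, is.null, TRUE)],
    filter_counts = as.list(out$filter_counts))
  manifest$config$sim <- if (!is.null(config$sim))
    unclass(config$sim)[!vapply(config$sim, is.null, TRUE)] else NULL
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(NULL)
}
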