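#' Validated run configuration
#'
#' Collects every tunable of the end-to-end pipeline. `unit_annotation` and
#' `sample_sheet` are file paths; numeric parameters are validated against
#' the ranges the individual stages accept.
#'
#' @param unit_annotation path to a BED/GFF3 unit annotation.
#' @param sample_sheet path to the sample sheet (see [read_sample_sheet()]).
#' @param out_dir output directory.
#' @param pseudocount,profile_window,ratio_window,velocity,min_prominence,min_distance
#'   pipeline parameters (see [compare_conditions()]).
#' @param ref_condition,test_condition optional condition labels.
#' @param seed integer seed recorded in the manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(unit_annotation, sample_sheet, out_dir,
                       pseudocount = 1, profile_window = 31,
                       ratio_window = 51, velocity = 40,
                       min_prominence = NULL, min_distance = 50,
                       ref_condition = NULL, test_condition = NULL,
                       seed = 1) {
  for (field in c("unit_annotation", "sample_sheet", "out_dir")) {
    v <- get(field)
    if (is.null(v) || !is.character(v) || length(v) != 1L || !nzchar(v))
      stop_validation("config field '", field, "' is missing or empty")
  }
  for (field in c("unit_annotation", "sample_sheet")) {
    if (!file.exists(get(field)))
      stop_validation("config field '", field, "' points to a missing file: ",
                      get(field))
  }
  if (!is_number(pseudocount) || pseudocount < 0)
    stop_validation("config field 'pseudocount' must be >= 0")
  if (!is_count(profile_window) || !is_count(ratio_window))
    stop_validation("config windows must be positive integers")
  if (!is_number(velocity) || velocity <= 0)
    stop_validation("config field 'velocity' must be > 0")
  structure(list(unit_annotation = unit_annotation,
                 sample_sheet = sample_sheet, out_dir = out_dir,
                 pseudocount = pseudocount, profile_window = profile_window,
                 ratio_window = ratio_window, velocity = velocity,
                 min_prominence = min_prominence,
                 min_distance = min_distance,
                 ref_condition = ref_condition,
                 test_condition = test_condition, seed = seed),
            class = "run_config")
}

#' Load a run configuration from JSON
#' @param path JSON file whose keys are [run_config()] arguments.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_parse("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

#' Run the full pipeline from a configuration
#'
#' profile -> aggregate -> compare -> report. The report directory contains
#' bedGraph tracks, TSV tables and a JSON manifest recording all parameters,
#' input md5 hashes and the package version; a rerun on identical inputs is
#' byte-identical. Any stage error aborts with the stage name.
#'
#' @param config a [run_config()] (or path to a JSON config).
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  unit <- stage("read_annotation", read_annotation(config$unit_annotation))
  sheet <- stage("read_sample_sheet", read_sample_sheet(config$sample_sheet))
  base <- dirname(config$sample_sheet)
  reads <- stage("read_alignments", {
    out <- lapply(seq_len(nrow(sheet)), function(i) {
      p <- sheet$path[i]
      if (!file.exists(p) && file.exists(file.path(base, p)))
        p <- file.path(base, p)
      read_alignments(p, format = tolower(sheet$format[i]), unit = unit)
    })
    names(out) <- sheet$sample_id
    out
  })
  cmp <- stage("compare_conditions", compare_conditions(
    reads, info = sheet, unit = unit,
    ref_condition = config$ref_condition,
    test_condition = config$test_condition,
    alpha = config$pseudocount, profile_window = config$profile_window,
    ratio_window = config$ratio_window, velocity = config$velocity,
    min_prominence = config$min_prominence,
    min_distance = config$min_distance))
  inputs <- c(config$unit_annotation, config$sample_sheet)
  stage("write_report", write_report(
    cmp, config$out_dir, inputs = inputs,
    extra_params = list(seed = config$seed,
                        unit_annotation = config$unit_annotation,
                        sample_sheet = config$sample_sheet)))
  invisible(config$out_dir)
}

#' One-command synthetic demonstration
#'
#' Simulates a wild-type / pause-attenuated condition pair from the default
#' rDNA-like world (7800-nt unit, 25-ms baseline dwell, 4x elevated dwell
#' over the first 1300 nt, discrete pause sites including initiation-
#' proximal +36 and terminator-proximal +7715 clusters, attenuation 0.5,
#' two replicates per condition), runs the full comparison pipeline, and
#' writes the report plus a truth-versus-estimate recovery table.
#'
#' @param seed master integer seed.
#' @param out_dir output directory.
#' @param n_reads reads per sample (default 2e5; the demo finishes in well
#'   under a minute).
#' @param pause_attenuation depletion strength in (0, 1] (default 0.5).
#' @return list with the `crac_comparison`, the `simulated_dataset`, the
#'   recovery `data.frame` and `out_dir` (invisible).
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("cracpause_demo"),
                     n_reads = 2e5, pause_attenuation = 0.5) {
  model <- demo_model()
  ds <- simulate_condition_pair(model, pause_attenuation = pause_attenuation,
                                n_replicates = 2, n_reads = n_reads,
                                unit = rdna_unit(), seed = seed)
  cmp <- compare_conditions(ds, ref_condition = "wildtype",
                            test_condition = "depleted")
  recovery <- recovery_table(cmp, ds)
  write_report(cmp, out_dir, extra_params = list(
    seed = seed, n_reads = n_reads, pause_attenuation = pause_attenuation))
  write.table(recovery, file.path(out_dir, "recovery.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(comparison = cmp, dataset = ds, recovery = recovery,
                 out_dir = out_dir))
}

#' Default demonstration world
#'
#' 7800-nt unit, baseline dwell 25 ms (the uniform occupancy at 40 nt/s),
#' 4-fold elevated dwell across the 1300-nt 5' block, and twelve pause loci
#' modeled as 7-nt clusters of elevated dwell (a polymerase pauses over a
#' footprint, and observed occupancy peaks are broader than one base): an
#' initiation-proximal locus at +36, three more in the 5' block, a strong
#' cluster across the internal spacer regions (where the wild-type smoothed
#' occupancy exceeds 150 ms against the 25-ms baseline), and a
#' terminator-proximal pile-up (+7550, +7715, +7790).
#' @return an `elongation_model`.
#' @export
demo_model <- function() {
  loci <- c(36, 450, 800, 1150, 3200, 3420, 3550, 3900, 4300,
            7550, 7715, 7790)
  mult <- c(12, 8, 8, 8, 30, 30, 30, 30, 30, 10, 15, 15)
  cluster <- -3:3
  build_dwell_profile(
    7800, baseline_dwell = 0.025,
    pause_positions = as.integer(outer(cluster, loci, `+`)),
    pause_multipliers = rep(mult, each = length(cluster)),
    ets5_enrichment = list(factor = 4, extent = 1300))
}

#' Truth-versus-estimate recovery table at the injected pause sites
#'
#' Compares the pipeline's occupancy-time estimates (reference condition)
#' against the truth at each injected pause position. The estimate is
#' intrinsically smoothed by the profile window, so truth columns are
#' smoothed with the same kernel. Two truth scales are reported:
#' `dwell_true_smoothed` (seconds a polymerase actually dwells; the
#' occupancy-time convention `fraction x t_total` underestimates it whenever
#' total dwell exceeds `t_total`, i.e. when pausing is heavy) and
#' `occupancy_truth` (the noise-free value of the estimator itself,
#' smoothed expected fraction x `t_total`); `rel_error` is taken against
#' the latter, isolating sampling/pseudocount error from that convention
#' bias.
#'
#' @param cmp a `crac_comparison`.
#' @param dataset the `simulated_dataset` it was computed from.
#' @return `data.frame` with one row per injected pause position.
#' @export
recovery_table <- function(cmp, dataset) {
  truth <- dataset$truth$wildtype
  w <- cmp$params$profile_window
  sm_truth <- smooth_blackman(truth$dwell, window = w)
  t_total <- cmp$params$t_total
  occ_truth <- smooth_blackman(expected_fractions(truth), w)$values * t_total
  pp <- truth$pause_positions
  est <- cmp$occupancy$ref$values[pp + 1L]
  data.frame(position = pp,
             multiplier = truth$pause_multipliers,
             dwell_true = truth$dwell[pp + 1L],
             dwell_true_smoothed = sm_truth[pp + 1L],
             occupancy_truth = occ_truth[pp + 1L],
             occupancy_estimate = est,
             rel_error = est / occ_truth[pp + 1L] - 1,
             dlog2 = cmp$dlog2$values[pp + 1L])
}
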