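#' Kinetic elongation model (per-position dwell times)
#'
#' Under steady-state transcription with independent polymerases and a
#' constant initiation flux, the expected density of active sites at a
#' position is proportional to the time a polymerase dwells there. The model
#' is therefore just a per-position dwell-time vector: a flat baseline,
#' optionally a uniformly elevated 5' block (mimicking strong 5'ETS
#' occupancy), and discrete pause sites whose dwell is the local baseline
#' times a multiplier >= 1.
#'
#' @param unit_length unit length in nucleotides.
#' @param baseline_dwell baseline dwell per nucleotide, seconds.
#' @param pause_positions 0-based unit coordinates of pause sites (unique,
#'   sorted, within `[0, unit_length)`).
#' @param pause_multipliers unitless factors >= 1, one per pause position.
#' @param ets5_enrichment optional `list(factor =, extent =)`: dwell in
#'   `[0, extent)` is multiplied by `factor` (>= 1) before pause multipliers
#'   are applied (multipliers act on the local baseline).
#' @return object of class `elongation_model` with fields `unit_length`,
#'   `dwell`, `baseline` (dwell without pause multipliers),
#'   `pause_positions`, `pause_multipliers`, `velocity_mean`
#'   (`unit_length / sum(dwell)`, nt/s).
#' @examples
#' m <- build_dwell_profile(7800, 0.025, pause_positions = c(36, 7715),
#'                          pause_multipliers = c(10, 10))
#' m$velocity_mean
#' @export
build_dwell_profile <- function(unit_length, baseline_dwell = 0.025,
                                pause_positions = integer(),
                                pause_multipliers = numeric(),
                                ets5_enrichment = NULL) {
  if (!is_count(unit_length)) stop_validation("unit_length must be a positive integer")
  if (!is_number(baseline_dwell) || baseline_dwell <= 0)
    stop_validation("baseline_dwell must be > 0")
  pause_positions <- as.integer(pause_positions)
  if (length(pause_positions) != length(pause_multipliers))
    stop_validation("one multiplier per pause position required")
  if (anyDuplicated(pause_positions))
    stop_validation("duplicate pause position ",
                    pause_positions[anyDuplicated(pause_positions)])
  if (any(pause_positions < 0L | pause_positions >= unit_length))
    stop_validation("pause position out of [0, ", unit_length, ")")
  if (any(pause_multipliers < 1))
    stop_validation("pause multipliers must be >= 1")
  ord <- order(pause_positions)
  pause_positions <- pause_positions[ord]
  pause_multipliers <- as.numeric(pause_multipliers[ord])
  baseline <- rep(baseline_dwell, unit_length)
  if (!is.null(ets5_enrichment)) {
    f <- ets5_enrichment$factor
    ext <- ets5_enrichment$extent
    if (!is_number(f) || f < 1) stop_validation("ets5 factor must be >= 1")
    if (!is_count(ext) || ext > unit_length)
      stop_validation("ets5 extent must be in [1, unit_length]")
    baseline[seq_len(ext)] <- baseline[seq_len(ext)] * f
  }
  dwell <- baseline
  dwell[pause_positions + 1L] <- baseline[pause_positions + 1L] * pause_multipliers
  structure(list(unit_length = as.integer(unit_length), dwell = dwell,
                 baseline = baseline, baseline_dwell = baseline_dwell,
                 pause_positions = pause_positions,
                 pause_multipliers = pause_multipliers,
                 ets5_enrichment = ets5_enrichment,
                 velocity_mean = unit_length / sum(dwell)),
            class = "elongation_model")
}

#' @rdname build_dwell_profile
#' @param dwell full per-position dwell vector (seconds, all > 0); an
#'   alternative constructor for arbitrary dwell landscapes.
#' @export
elongation_model <- function(dwell, pause_positions = integer(),
                             pause_multipliers = numeric()) {
  dwell <- as.numeric(dwell)
  if (!length(dwell) || any(!is.finite(dwell)) || any(dwell <= 0))
    stop_validation("dwell times must be strictly positive and finite")
  L <- length(dwell)
  pause_positions <- as.integer(pause_positions)
  if (any(pause_positions < 0L | pause_positions >= L))
    stop_validation("pause position out of [0, ", L, ")")
  baseline <- dwell
  if (length(pause_positions))
    baseline[pause_positions + 1L] <- dwell[pause_positions + 1L] /
      pause_multipliers
  structure(list(unit_length = L, dwell = dwell, baseline = baseline,
                 baseline_dwell = stats::median(baseline),
                 pause_positions = pause_positions,
                 pause_multipliers = as.numeric(pause_multipliers),
                 ets5_enrichment = NULL,
                 velocity_mean = L / sum(dwell)),
            class = "elongation_model")
}

#' @export
print.elongation_model <- function(x, ...) {
  cat(sprintf("<elongation_model> %d nt, total dwell %.4g s, mean velocity %.4g nt/s\n",
              x$unit_length, sum(x$dwell), x$velocity_mean))
  if (length(x$pause_positions))
    cat(sprintf("pauses: %d sites (multipliers %.3g-%.3g)\n",
                length(x$pause_positions), min(x$pause_multipliers),
                max(x$pause_multipliers)))
  invisible(x)
}

#' Analytic steady-state 3'-end fractions of an elongation model
#'
#' With independent polymerases at constant initiation flux, the expected
#' fraction of read 3' ends at position i is `dwell_i / sum(dwell)`.
#'
#' @param model an `elongation_model`.
#' @return `position_profile` of kind `"fraction"` (sums to 1).
#' @export
expected_fractions <- function(model) {
  stopifnot(inherits(model, "elongation_model"))
  position_profile(model$dwell / sum(model$dwell), "fraction",
                   meta = list(source = "expected_fractions"))
}

#' Read-length sampler specification
#'
#' `"geometric"`: `min + rgeom(p)` with `p` chosen so the mean is `mean`
#' (default mean 30 nt, min 15 nt — plausible CRAC insert sizes).
#' `"fixed"`: constant `length`.
#'
#' @param type `"geometric"` or `"fixed"`.
#' @param mean,min geometric parameters (nucleotides).
#' @param length fixed length (nucleotides).
#' @return a sampler spec list used by [simulate_reads()].
#' @export
read_length_spec <- function(type = c("geometric", "fixed"), mean = 30,
                             min = 15, length = 30) {
  type <- match.arg(type)
  if (type == "geometric") {
    if (!is_number(mean) || !is_number(min) || min < 1 || mean < min)
      stop_validation("need 1 <= min <= mean for geometric read lengths")
    list(type = "geometric", mean = mean, min = min)
  } else {
    if (!is_count(length)) stop_validation("fixed read length must be a positive integer")
    list(type = "fixed", length = length)
  }
}

sample_read_lengths <- function(spec, n) {
  switch(spec$type,
    geometric = {
      p <- 1 / (spec$mean - spec$min + 1)
      spec$min + rgeom(n, prob = p)
    },
    fixed = rep(spec$length, n),
    stop_validation("unknown read-length spec type '", spec$type, "'"))
}

#' Simulate CRAC-style reads from an elongation model
#'
#' Read 3'-end unit positions are drawn multinomially from
#' [expected_fractions()]; each read extends upstream from its 3' end by a
#' sampled length, truncated at the unit's 5' boundary, and carries the
#' unit's strand. Genomic coordinates honor strand orientation: the 3' end
#' maps to the rightmost base for plus-strand units and the leftmost base
#' for minus-strand units.
#'
#' @param model an `elongation_model`.
#' @param unit a [transcription_unit()] with `unit_length(unit) ==
#'   model$unit_length`.
#' @param n_reads number of reads to draw.
#' @param read_length a [read_length_spec()].
#' @param seed optional integer seed (caller RNG state is restored).
#' @return `GRanges` of reads with `weight = 1` and a `name` column.
#' @export
simulate_reads <- function(model, unit, n_reads,
                           read_length = read_length_spec(), seed = NULL) {
  stopifnot(inherits(model, "elongation_model"),
            inherits(unit, "transcription_unit"))
  if (unit$length != model$unit_length)
    stop_validation("unit length (", unit$length,
                    ") does not match model (", model$unit_length, ")")
  if (!is_count(n_reads)) stop_validation("n_reads must be a positive integer")
  f <- expected_fractions(model)$values
  with_seed(seed, {
    p3 <- sample.int(model$unit_length, size = n_reads, replace = TRUE,
                     prob = f) - 1L
    len <- sample_read_lengths(read_length, n_reads)
    if (any(len < 1)) stop_validation("read-length sampler produced nonpositive lengths")
    span <- pmin(len, p3 + 1L)            # truncate at the unit 5' boundary
    ustart <- p3 - span + 1L              # unit-coordinate read interval [ustart, p3]
    if (unit$strand == "+") {
      gs0 <- unit$start + ustart          # 0-based half-open genomic
      ge0 <- unit$start + p3 + 1L
    } else {
      gs0 <- unit$end - 1L - p3
      ge0 <- unit$end - ustart
    }
    gr <- GenomicRanges::GRanges(
      seqnames = unit$chrom,
      ranges = IRanges(start = gs0 + 1L, end = ge0),
      strand = unit$strand)
    mcols(gr)$name <- sprintf("read_%06d", seq_len(n_reads))
    mcols(gr)$score <- 0L
    mcols(gr)$weight <- rep(1, n_reads)
    gr
  })
}

#' @export
simulate.elongation_model <- function(object, nsim = 1000, seed = NULL, ...,
                                      unit = NULL) {
  if (is.null(unit))
    unit <- transcription_unit("rDNA", 0, object$unit_length, "+")
  simulate_reads(object, unit, n_reads = nsim, seed = seed, ...)
}

#' Simulate a wild-type / depleted condition pair
#'
#' The depleted condition attenuates every pause: multiplier `m` becomes
#' `m' = 1 + attenuation * (m - 1)` (attenuation 1 leaves the model
#' unchanged; smaller values weaken pausing, mimicking loss of a pausing
#' factor). Each (condition, replicate) sample is simulated with an
#' independent seed derived deterministically from the master seed.
#'
#' @param model_wt wild-type `elongation_model`.
#' @param pause_attenuation factor in (0, 1].
#' @param n_replicates biological replicates per condition (default 2).
#' @param n_reads reads per sample.
#' @param unit optional [transcription_unit()] (default: plus-strand unit
#'   `rDNA:0-L`).
#' @param read_length a [read_length_spec()].
#' @param seed master integer seed.
#' @return object of class `simulated_dataset`: `reads_by_sample` (named
#'   list of `GRanges`), `info` (sample sheet data.frame), `truth` (list of
#'   the two models), `unit`, `seed`, `n_reads`.
#' @export
simulate_condition_pair <- function(model_wt, pause_attenuation = 0.5,
                                    n_replicates = 2, n_reads = 5e5,
                                    unit = NULL,
                                    read_length = read_length_spec(),
                                    seed = 1) {
  stopifnot(inherits(model_wt, "elongation_model"))
  if (!is_number(pause_attenuation) || pause_attenuation <= 0 ||
      pause_attenuation > 1)
    stop_validation("pause_attenuation must be in (0, 1]")
  if (!is_count(n_replicates)) stop_validation("n_replicates must be >= 1")
  if (is.null(unit))
    unit <- transcription_unit("rDNA", 0, model_wt$unit_length, "+")
  model_dep <- attenuate_pauses(model_wt, pause_attenuation)
  truth <- list(wildtype = model_wt, depleted = model_dep)
  reads <- list()
  info <- NULL
  for (ci in seq_along(truth)) {
    cond <- names(truth)[ci]
    for (r in seq_len(n_replicates)) {
      sid <- sprintf("%s_rep%d", cond, r)
      s <- derive_seed(seed, ci, r)
      reads[[sid]] <- simulate_reads(truth[[ci]], unit, n_reads,
                                     read_length = read_length, seed = s)
      info <- rbind(info, data.frame(sample_id = sid, condition = cond,
                                     replicate = r, seed = s))
    }
  }
  structure(list(reads_by_sample = reads, info = info, truth = truth,
                 unit = unit, seed = seed, n_reads = n_reads,
                 pause_attenuation = pause_attenuation),
            class = "simulated_dataset")
}

#' Attenuate the pause multipliers of a model
#' @param model an `elongation_model` built by [build_dwell_profile()].
#' @param attenuation factor in (0, 1]; `m' = 1 + attenuation * (m - 1)`.
#' @return a new `elongation_model`.
#' @export
attenuate_pauses <- function(model, attenuation) {
  m2 <- 1 + attenuation * (model$pause_multipliers - 1)
  dwell <- model$baseline
  if (length(model$pause_positions))
    dwell[model$pause_positions + 1L] <-
      model$baseline[model$pause_positions + 1L] * m2
  out <- model
  out$dwell <- dwell
  out$pause_multipliers <- m2
  out$velocity_mean <- model$unit_length / sum(dwell)
  out
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d samples x %d reads, attenuation %.3g, seed %d\n",
              length(x$reads_by_sample), x$n_reads, x$pause_attenuation,
              x$seed))
  print(x$info)
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Reads go to BED6 (one file per sample), the ground-truth dwell profiles
#' to bedGraph (seconds per position), and pause positions/multipliers/seed
#' to a JSON sidecar.
#'
#' @param dataset a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(dataset$reads_by_sample))
    rtracklayer::export(dataset$reads_by_sample[[sid]],
                        file.path(dir, paste0(sid, ".bed")), format = "BED")
  for (cond in names(dataset$truth)) {
    m <- dataset$truth[[cond]]
    write_track(position_profile(m$dwell, "occupancy_time_seconds"),
                dataset$unit, file.path(dir, paste0("truth_", cond,
                                                    "_dwell.bedgraph")))
  }
  sidecar <- list(
    seed = dataset$seed, n_reads = dataset$n_reads,
    pause_attenuation = dataset$pause_attenuation,
    truth = lapply(dataset$truth, function(m)
      list(pause_positions = m$pause_positions,
           pause_multipliers = m$pause_multipliers,
           baseline_dwell = m$baseline_dwell,
           velocity_mean = m$velocity_mean)))
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate ChIP-qPCR technical replicates with known enrichment
#'
#' Generates CT values such that the noise-free [chip_enrichment()] with
#' dilution correction recovers `true_enrichment` exactly (with equal
#' dilutions the uncorrected value recovers it too).
#'
#' @param true_enrichment programmed fold enrichment (> 0).
#' @param ct_reference input CT level, cycles.
#' @param dilution_ip,dilution_input fold dilutions (defaults 20 and 100).
#' @param noise_sd per-replicate Gaussian CT noise, cycles.
#' @param n_technical technical replicates (default 3).
#' @param seed optional seed.
#' @param amplicon label.
#' @return a [qpcr_measurement()].
#' @export
simulate_qpcr <- function(true_enrichment, ct_reference = 20,
                          dilution_ip = 20, dilution_input = 100,
                          noise_sd = 0, n_technical = 3, seed = NULL,
                          amplicon = "amplicon") {
  if (!is_number(true_enrichment) || true_enrichment <= 0)
    stop_validation("true_enrichment must be > 0")
  if (dilution_ip <= 0 || dilution_input <= 0)
    stop_validation("dilutions must be > 0")
  with_seed(seed, {
    ct_input <- ct_reference + rnorm(n_technical, 0, noise_sd)
    ct_ip <- ct_reference -
      log2(true_enrichment * dilution_ip / dilution_input) +
      rnorm(n_technical, 0, noise_sd)
    qpcr_measurement(ct_ip = ct_ip, ct_input = ct_input,
                     dilution_ip = dilution_ip,
                     dilution_input = dilution_input, amplicon = amplicon)
  })
}
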