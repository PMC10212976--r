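#' Compare two conditions along a transcription unit
#'
#' Runs the full per-sample pipeline (3'-end counts, pseudocounts,
#' fractions), aggregates replicates (median with Q2-Q3 band) on
#' `profile_window`-smoothed fractions, forms the log2 depleted/reference
#' ratio track from `ratio_window`-smoothed condition medians, converts the
#' smoothed condition medians to occupancy time, calls pause sites per
#' condition, and summarizes fractions per annotated region. Pause sites are
#' matched across conditions by nearest position within `min_distance`.
#'
#' @param samples either a `simulated_dataset` (from
#'   [simulate_condition_pair()]) or a named list of read `GRanges`, one per
#'   sample.
#' @param info sample sheet `data.frame` with `sample_id`, `condition`,
#'   `replicate` (ignored when `samples` is a `simulated_dataset`).
#' @param unit a [transcription_unit()] (ignored for a `simulated_dataset`,
#'   which carries its own).
#' @param ref_condition,test_condition condition labels; by default the
#'   first and second unique condition in `info`.
#' @param alpha pseudocount per position (default 1).
#' @param profile_window Blackman window for display/occupancy profiles
#'   (default 31 nt).
#' @param ratio_window Blackman window applied before the log2 ratio
#'   (default 51 nt).
#' @param velocity mean elongation velocity for occupancy time, nt/s.
#' @param min_prominence,min_distance pause-caller settings
#'   (see [detect_pauses()]).
#' @return object of class `crac_comparison`; see Details.
#' @details The returned object bundles: `aggregate` (per condition, the
#'   smoothed-fraction `aggregate_profile`), `fractions` (per sample,
#'   unsmoothed), `dlog2` (test over reference), `occupancy` (per
#'   condition), `pauses` (per condition), `pause_matches` (test vs
#'   reference pause table), `regions` (per-condition region sums of
#'   unsmoothed median fractions with delta and log2 fold change), `params`.
#' @export
compare_conditions <- function(samples, info = NULL, unit = NULL,
                               ref_condition = NULL, test_condition = NULL,
                               alpha = 1, profile_window = 31,
                               ratio_window = 51, velocity = 40,
                               min_prominence = NULL, min_distance = 50) {
  if (inherits(samples, "simulated_dataset")) {
    info <- samples$info
    unit <- samples$unit
    samples <- samples$reads_by_sample
  }
  if (is.null(info) || is.null(unit))
    stop_validation("info and unit are required unless samples is a simulated_dataset")
  stopifnot(inherits(unit, "transcription_unit"))
  conds <- unique(info$condition)
  if (length(conds) < 2L)
    stop_validation("need two conditions, found: ",
                    paste(conds, collapse = ", "))
  ref_condition <- ref_condition %||% conds[1L]
  test_condition <- test_condition %||% setdiff(conds, ref_condition)[1L]
  for (cond in c(ref_condition, test_condition))
    if (!cond %in% conds)
      stop_validation("condition '", cond, "' not present in sample info")
  missing_samples <- setdiff(info$sample_id, names(samples))
  if (length(missing_samples))
    stop_validation("reads missing for sample(s): ",
                    paste(missing_samples, collapse = ", "))

  # per-sample unsmoothed fractions from pseudocounted 3'-end counts
  fractions <- lapply(info$sample_id, function(sid) {
    p <- count_three_prime_ends(samples[[sid]], unit)
    p <- add_pseudocounts(p, alpha)
    p <- to_fractions(p)
    p$meta$sample_id <- sid
    p$meta$condition <- info$condition[info$sample_id == sid]
    p$meta$replicate <- info$replicate[info$sample_id == sid]
    p
  })
  names(fractions) <- info$sample_id

  by_cond <- function(cond) fractions[info$sample_id[info$condition == cond]]
  smooth_all <- function(ps, w) lapply(ps, smooth_blackman, window = w)
  agg_or_single <- function(ps) {
    if (length(ps) >= 2L) aggregate_replicates(ps) else
      structure(list(median = ps[[1L]]$values, band_low = ps[[1L]]$values,
                     band_high = ps[[1L]]$values, n_replicates = 1L,
                     kind = ps[[1L]]$kind, meta = ps[[1L]]$meta),
                class = "aggregate_profile")
  }

  conditions <- stats::setNames(list(ref_condition, test_condition),
                                c("ref", "test"))
  aggregate <- lapply(conditions, function(cond)
    agg_or_single(smooth_all(by_cond(cond), profile_window)))
  ratio_med <- lapply(conditions, function(cond)
    median_profile(agg_or_single(smooth_all(by_cond(cond), ratio_window))))
  for (k in names(ratio_med)) ratio_med[[k]]$meta$condition <- conditions[[k]]
  dlog2 <- log2_ratio(ratio_med$test, ratio_med$ref, window = 1)
  dlog2$meta$window <- ratio_window

  params <- occupancy_parameters(unit$length, velocity)
  occupancy <- lapply(aggregate, function(a)
    occupancy_time(median_profile(a), params))

  pauses <- lapply(aggregate, function(a)
    detect_pauses(median_profile(a), min_prominence = min_prominence,
                  min_distance = min_distance))

  pause_matches <- match_pauses(pauses$test, pauses$ref, min_distance)
  pause_matches$dlog2_at_test <- ifelse(
    is.na(pause_matches$position_test), NA_real_,
    dlog2$values[pause_matches$position_test + 1L])

  med_frac <- lapply(conditions, function(cond)
    agg_or_single(by_cond(cond))$median)
  regions <- region_summary(med_frac$ref, unit)
  regions$sum_ref <- regions$sum
  regions$sum_test <- region_summary(med_frac$test, unit)$sum
  regions$sum <- NULL
  regions$mean <- NULL
  regions$delta <- regions$sum_test - regions$sum_ref
  regions$log2_fc <- log2(regions$sum_test / regions$sum_ref)

  structure(list(
    unit = unit, conditions = conditions, fractions = fractions,
    aggregate = aggregate, dlog2 = dlog2, occupancy = occupancy,
    pauses = pauses, pause_matches = pause_matches, regions = regions,
    params = list(alpha = alpha, profile_window = profile_window,
                  ratio_window = ratio_window, velocity = velocity,
                  t_total = params$t_total,
                  min_prominence = min_prominence,
                  min_distance = min_distance,
                  ref_condition = ref_condition,
                  test_condition = test_condition)),
    class = "crac_comparison")
}

# Match test pauses to the nearest reference pause within max_dist.
match_pauses <- function(test, ref, max_dist) {
  if (!nrow(test) && !nrow(ref))
    return(data.frame(position_test = integer(), position_ref = integer(),
                      score_test = numeric(), score_ref = numeric(),
                      distance = integer()))
  used <- logical(nrow(ref))
  rows <- lapply(seq_len(nrow(test)), function(i) {
    d <- abs(ref$position - test$position[i])
    d[used] <- Inf
    j <- if (nrow(ref)) which.min(d) else integer(0)
    if (length(j) && is.finite(d[j]) && d[j] <= max_dist) {
      used[j] <<- TRUE
      data.frame(position_test = test$position[i],
                 position_ref = ref$position[j],
                 score_test = test$score[i], score_ref = ref$score[j],
                 distance = as.integer(d[j]))
    } else {
      data.frame(position_test = test$position[i],
                 position_ref = NA_integer_, score_test = test$score[i],
                 score_ref = NA_real_, distance = NA_integer_)
    }
  })
  out <- do.call(rbind, rows)
  if (any(!used)) {
    extra <- data.frame(position_test = NA_integer_,
                        position_ref = ref$position[!used],
                        score_test = NA_real_, score_ref = ref$score[!used],
                        distance = NA_integer_)
    out <- rbind(out, extra)
  }
  out
}

#' @export
print.crac_comparison <- function(x, ...) {
  cat(sprintf("<crac_comparison> %s vs %s over %s (%d nt)\n",
              x$conditions$test, x$conditions$ref, x$unit$name,
              x$unit$length))
  cat(sprintf("  pause sites: %d (%s), %d (%s); t_total = %.6g s\n",
              nrow(x$pauses$test), x$conditions$test, nrow(x$pauses$ref),
              x$conditions$ref, x$params$t_total))
  cat(sprintf("  mean delta-log2 over unit: %.4f\n", mean(x$dlog2$values)))
  invisible(x)
}

#' @export
summary.crac_comparison <- function(object, ...) {
  cat(sprintf("Comparison of %s (test) vs %s (reference)\n",
              object$conditions$test, object$conditions$ref))
  cat("\nRegion summary (fractions of reads):\n")
  print(object$regions, digits = 4)
  cat("\nMatched pause sites:\n")
  print(object$pause_matches, digits = 4)
  invisible(object)
}

#' @export
plot.crac_comparison <- function(x, ...) {
  pos <- seq_len(x$unit$length) - 1L
  old <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  ymax <- max(x$aggregate$ref$band_high, x$aggregate$test$band_high)
  graphics::plot(pos, x$aggregate$ref$median, type = "l", col = "darkgreen",
                 ylim = c(0, ymax), xlab = "unit position (nt)",
                 ylab = "smoothed fraction of reads",
                 main = "3'-end occupancy profiles", ...)
  graphics::lines(pos, x$aggregate$test$median, col = "steelblue")
  graphics::legend("topright", bty = "n", lty = 1,
                   col = c("darkgreen", "steelblue"),
                   legend = c(x$conditions$ref, x$conditions$test))
  graphics::plot(pos, x$dlog2$values, type = "l", col = "grey30",
                 xlab = "unit position (nt)", ylab = "log2(test / ref)",
                 main = "log2 ratio track")
  graphics::abline(h = 0, lty = 2)
  if (nrow(x$pauses$ref))
    graphics::abline(v = x$pauses$ref$position, col = "orange", lty = 3)
  graphics::plot(pos, x$occupancy$ref$values, type = "l", col = "darkgreen",
                 xlab = "unit position (nt)", ylab = "occupancy time (s)",
                 main = "per-position occupancy time")
  graphics::lines(pos, x$occupancy$test$values, col = "steelblue")
  invisible(x)
}

#' Write a comparison report directory
#'
#' bedGraph tracks (condition medians, log2 ratio, occupancy times), TSV
#' pause and region tables, and a JSON manifest of every parameter.
#'
#' @param x a `crac_comparison`.
#' @param dir output directory (created).
#' @param inputs optional input files to hash into the manifest.
#' @param extra_params optional extra manifest entries (e.g. seed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir, inputs = NULL, extra_params = list()) {
  stopifnot(inherits(x, "crac_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  u <- x$unit
  write_track(median_profile(x$aggregate$ref), u,
              file.path(dir, "profile_ref.bedgraph"), name = "median_ref")
  write_track(median_profile(x$aggregate$test), u,
              file.path(dir, "profile_test.bedgraph"), name = "median_test")
  write_track(x$dlog2, u, file.path(dir, "dlog2.bedgraph"), name = "dlog2")
  write_track(x$occupancy$ref, u,
              file.path(dir, "occupancy_ref.bedgraph"), name = "occupancy_ref")
  write_track(x$occupancy$test, u,
              file.path(dir, "occupancy_test.bedgraph"),
              name = "occupancy_test")
  tsv <- function(df, file) write.table(
    df, file.path(dir, file), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(x$pauses$ref, "pauses_ref.tsv")
  tsv(x$pauses$test, "pauses_test.tsv")
  tsv(x$pause_matches, "pause_matches.tsv")
  tsv(x$regions, "region_summary.tsv")
  write_manifest(c(x$params, extra_params), inputs,
                 file.path(dir, "manifest.json"))
  invisible(dir)
}
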