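#' Occupancy-time parameters
#'
#' The total transcription (occupancy) time of the unit is
#' `t_total = unit_length / velocity`; per-position occupancy time is the
#' fraction of read 3' ends at that position times `t_total`. Defaults are
#' the rDNA constants: 7800 nt and 40 nt/s, giving `t_total = 195` s.
#'
#' @param unit_length unit length, nucleotides (default 7800).
#' @param velocity mean elongation velocity, nt/s (default 40).
#' @return object of class `occupancy_parameters` with computed `t_total`.
#' @export
occupancy_parameters <- function(unit_length = 7800, velocity = 40) {
  if (!is_count(unit_length)) stop_validation("unit_length must be a positive integer")
  if (!is_number(velocity) || velocity <= 0)
    stop_validation("velocity must be > 0")
  structure(list(unit_length = as.integer(unit_length), velocity = velocity,
                 t_total = unit_length / velocity),
            class = "occupancy_parameters")
}

#' @export
print.occupancy_parameters <- function(x, ...) {
  cat(sprintf("<occupancy_parameters> %d nt / %.4g nt/s -> t_total = %.6g s\n",
              x$unit_length, x$velocity, x$t_total))
  invisible(x)
}

#' Convert a fraction profile to per-position occupancy time
#'
#' `t_i = f_i * t_total` (seconds). For a raw fraction profile the track
#' sums to `t_total` exactly; smoothed fractions are accepted with a wider
#' sum tolerance because edge renormalization perturbs total mass slightly.
#'
#' @param profile `position_profile` of kind `"fraction"` or
#'   `"smoothed_fraction"`.
#' @param params an [occupancy_parameters()].
#' @return `position_profile` of kind `"occupancy_time_seconds"`.
#' @examples
#' p <- position_profile(rep(1 / 7800, 7800), "fraction")
#' ot <- occupancy_time(p, occupancy_parameters())
#' sum(ot$values)      # 195 s
#' ot$values[1]        # 0.025 s = 25 ms per position
#' @export
occupancy_time <- function(profile, params = occupancy_parameters()) {
  stopifnot(inherits(profile, "position_profile"),
            inherits(params, "occupancy_parameters"))
  if (!profile$kind %in% c("fraction", "smoothed_fraction"))
    stop_validation("occupancy_time expects a (smoothed) fraction profile, got ",
                    profile$kind)
  tol <- if (profile$kind == "fraction") 1e-6 else 0.02
  if (abs(sum(profile$values) - 1) > tol)
    stop_validation("fraction profile sums to ",
                    format(sum(profile$values), digits = 10), ", not 1")
  meta <- profile$meta
  meta$t_total <- params$t_total
  meta$velocity <- params$velocity
  position_profile(profile$values * params$t_total, "occupancy_time_seconds",
                   meta)
}

#' Log2 ratio track between two conditions
#'
#' Both inputs are smoothed with the stated Blackman window (default 51 nt),
#' then `log2(smooth(test) / smooth(ref))` is taken per position. Inputs
#' must be strictly positive after smoothing — guaranteed when fractions
#' were computed from pseudocounted counts. `window = 1` skips smoothing.
#'
#' @param profile_test,profile_ref `position_profile`s of kind `"fraction"`
#'   (or already-smoothed fractions), equal length.
#' @param window smoothing window, nucleotides (default 51).
#' @return `position_profile` of kind `"log2_ratio"`.
#' @export
log2_ratio <- function(profile_test, profile_ref, window = 51) {
  stopifnot(inherits(profile_test, "position_profile"),
            inherits(profile_ref, "position_profile"))
  if (length(profile_test$values) != length(profile_ref$values))
    stop_validation("profiles have different lengths")
  smooth1 <- function(p) {
    if (window == 1) p$values else smooth_blackman(p, window)$values
  }
  ts <- smooth1(profile_test)
  rs <- smooth1(profile_ref)
  if (any(ts <= 0) || any(rs <= 0))
    stop_validation("nonpositive smoothed values; compute fractions from ",
                    "pseudocounted counts (add_pseudocounts) first")
  position_profile(log2(ts / rs), "log2_ratio",
                   meta = list(window = window,
                               test = profile_test$meta$condition,
                               ref = profile_ref$meta$condition))
}

#' Call pause sites as prominent local maxima
#'
#' Local maxima (leftmost position of a plateau; unit boundaries excluded)
#' are scored by topographic prominence — peak height above the higher of
#' the two flanking minima, each taken up to the nearest higher point or
#' boundary. Peaks with prominence below `min_prominence` are dropped, then
#' peaks closer than `min_distance` to a higher kept peak are removed
#' (ties: lower position wins). By default `min_prominence` is 0.25 x the
#' profile median: the default 31-nt Blackman kernel attenuates a
#' single-nucleotide pause of multiplier m to a bump of about
#' (m - 1)/13 x baseline, so 0.25 x median calls pauses with m of roughly 4
#' and above while sitting far above sampling noise at realistic depths.
#'
#' @param profile smoothed `position_profile` (or numeric vector).
#' @param min_prominence minimum prominence, same units as the profile;
#'   `NULL` = 0.25 x median(profile).
#' @param min_distance minimum separation between called sites, nt.
#' @return `data.frame` with columns `position` (0-based unit coordinate),
#'   `score` (profile value at the peak), `prominence`, `width`
#'   (nucleotides above half-prominence), sorted by position. Zero rows when
#'   nothing passes.
#' @export
detect_pauses <- function(profile, min_prominence = NULL, min_distance = 50) {
  x <- profile_values(profile)
  n <- length(x)
  if (is.null(min_prominence)) min_prominence <- 0.25 * median(x)
  if (!is_number(min_prominence) || min_prominence < 0)
    stop_validation("min_prominence must be a nonnegative number")
  empty <- data.frame(position = integer(), score = numeric(),
                      prominence = numeric(), width = integer())
  if (n < 3L) return(empty)
  # collapse plateaus to runs; run j is a peak if both neighbours are lower
  r <- rle(x)
  nruns <- length(r$values)
  if (nruns < 3L) return(empty)
  run_start <- cumsum(c(1L, r$lengths[-nruns]))
  inner <- 2:(nruns - 1L)
  is_peak <- r$values[inner] > r$values[inner - 1L] &
    r$values[inner] > r$values[inner + 1L]
  peaks <- run_start[inner][is_peak]        # leftmost index of plateau (1-based)
  if (!length(peaks)) return(empty)
  prom <- vapply(peaks, function(p) {
    h <- x[p]
    li <- p - 1L
    lmin <- h
    while (li >= 1L && x[li] <= h) { lmin <- min(lmin, x[li]); li <- li - 1L }
    ri <- p + 1L
    rmin <- h
    while (ri <= n && x[ri] <= h) { rmin <- min(rmin, x[ri]); ri <- ri + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  peaks <- peaks[keep]; prom <- prom[keep]
  if (!length(peaks)) return(empty)
  # enforce min_distance: highest first, ties to the leftmost
  ord <- order(-x[peaks], peaks)
  kept <- logical(length(peaks))
  kept_pos <- integer(0)
  for (i in ord) {
    if (!length(kept_pos) || all(abs(kept_pos - peaks[i]) >= min_distance)) {
      kept[i] <- TRUE
      kept_pos <- c(kept_pos, peaks[i])
    }
  }
  peaks <- peaks[kept]; prom <- prom[kept]
  width <- mapply(function(p, pr) {
    half <- x[p] - pr / 2
    li <- p
    while (li > 1L && x[li - 1L] >= half && x[li - 1L] <= x[p]) li <- li - 1L
    ri <- p
    while (ri < n && x[ri + 1L] >= half && x[ri + 1L] <= x[p]) ri <- ri + 1L
    ri - li + 1L
  }, peaks, prom)
  ord <- order(peaks)
  data.frame(position = peaks[ord] - 1L, score = x[peaks][ord],
             prominence = prom[ord], width = as.integer(width[ord]))
}

#' Per-region summary of a profile
#'
#' Sums and means of the profile over each named subregion of the unit,
#' plus an `(outside)` row covering positions not assigned to any region
#' (present only when such positions exist). For a fraction profile the
#' `sum` column plus the outside row totals 1.
#'
#' @param profile `position_profile` or numeric vector of unit length.
#' @param unit a [transcription_unit()] with regions.
#' @return `data.frame` with columns `region`, `start`, `end`, `length`,
#'   `sum`, `mean`.
#' @export
region_summary <- function(profile, unit) {
  stopifnot(inherits(unit, "transcription_unit"))
  x <- profile_values(profile)
  if (length(x) != unit$length)
    stop_validation("profile length (", length(x),
                    ") does not match unit length (", unit$length, ")")
  reg <- unit$regions
  covered <- logical(unit$length)
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    idx <- (reg$start[i] + 1L):reg$end[i]
    covered[idx] <<- TRUE
    data.frame(region = reg$name[i], start = reg$start[i], end = reg$end[i],
               length = length(idx), sum = sum(x[idx]), mean = mean(x[idx]))
  })
  out <- do.call(rbind, rows)
  if (!all(covered)) {
    idx <- which(!covered)
    out <- rbind(out, data.frame(region = "(outside)", start = NA_integer_,
                                 end = NA_integer_, length = length(idx),
                                 sum = sum(x[idx]), mean = mean(x[idx])))
  }
  rownames(out) <- NULL
  out
}

#' Intersect two identifier lists
#'
#' Identifiers are normalized (default: trimmed and lower-cased) and
#' deduplicated before intersecting, so the counts refer to unique
#' normalized identifiers.
#'
#' @param list_a,list_b character vectors of identifiers (nonempty).
#' @param normalizer function applied to both lists before comparison.
#' @return list with `intersection` (sorted normalized ids), `n_a`, `n_b`,
#'   `n_common`.
#' @export
intersect_id_lists <- function(list_a, list_b,
                               normalizer = function(x) tolower(trimws(x))) {
  if (!length(list_a) || !length(list_b))
    stop_validation("identifier lists must be nonempty")
  a <- unique(normalizer(as.character(list_a)))
  b <- unique(normalizer(as.character(list_b)))
  common <- sort(intersect(a, b))
  list(intersection = common, n_a = length(a), n_b = length(b),
       n_common = length(common))
}
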