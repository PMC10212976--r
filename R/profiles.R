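#' Per-nucleotide position profile
#'
#' A numeric track over a transcription unit, one value per nucleotide.
#' `kind` records what the values are: raw 3'-end `count`s, `fraction` of
#' reads (sums to 1), `smoothed_fraction`, `occupancy_time_seconds`, or a
#' `log2_ratio` between conditions. Note that edge-renormalized smoothing
#' conserves total mass only approximately, so the sum-to-one invariant is
#' enforced for `fraction` but not `smoothed_fraction`.
#'
#' @param values numeric vector, one value per unit position.
#' @param kind one of `"count"`, `"fraction"`, `"smoothed_fraction"`,
#'   `"occupancy_time_seconds"`, `"log2_ratio"`.
#' @param meta named list of metadata (sample_id, condition, replicate,
#'   window, pseudocount, ...).
#' @return object of class `position_profile` (fields `values`, `kind`,
#'   `meta`).
#' @export
position_profile <- function(values,
                             kind = c("count", "fraction", "smoothed_fraction",
                                      "occupancy_time_seconds", "log2_ratio"),
                             meta = list()) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (!length(values) || anyNA(values) || any(!is.finite(values)))
    stop_validation("profile values must be finite and non-empty")
  if (kind %in% c("count", "fraction", "smoothed_fraction") && any(values < 0))
    stop_validation("negative values in a ", kind, " profile")
  if (kind == "fraction" && abs(sum(values) - 1) > 1e-9)
    stop_validation("fraction profile must sum to 1 (got ",
                    format(sum(values), digits = 12), ")")
  structure(list(values = values, kind = kind, meta = meta),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, ...) {
  cat(sprintf("<position_profile> kind=%s, length=%d\n", x$kind,
              length(x$values)))
  m <- x$meta[!vapply(x$meta, is.null, logical(1))]
  if (length(m))
    cat("meta:", paste(names(m), unlist(lapply(m, format)), sep = "=",
                       collapse = ", "), "\n")
  cat("values:", paste(format(head(x$values, 6), digits = 4), collapse = " "),
      if (length(x$values) > 6) "...\n" else "\n")
  invisible(x)
}

#' @export
length.position_profile <- function(x) length(x$values)

profile_values <- function(x) {
  if (inherits(x, "position_profile")) x$values
  else if (is.numeric(x)) as.numeric(x)
  else stop_validation("expected a position_profile or numeric vector")
}

#' Count read 3' ends per unit position
#'
#' `values[p]` is the summed weight of reads whose 3' end maps to unit
#' position `p`; reads outside the unit (NA positions) are ignored, so the
#' profile total equals the total in-unit read weight.
#'
#' @param reads `GRanges` of alignments (optional `weight` column).
#' @param unit a [transcription_unit()].
#' @return `position_profile` of kind `"count"`.
#' @export
count_three_prime_ends <- function(reads, unit) {
  stopifnot(inherits(unit, "transcription_unit"))
  v <- numeric(unit$length)
  if (length(reads)) {
    pos <- to_unit_coordinates(reads, unit)
    w <- read_weights(reads)
    keep <- !is.na(pos)
    if (any(keep)) {
      sums <- rowsum(w[keep], group = pos[keep] + 1L)
      v[as.integer(rownames(sums))] <- sums[, 1L]
    }
  }
  position_profile(v, "count")
}

#' Add pseudocounts to a count profile
#'
#' Adds `alpha` to every position so downstream fractions and log-ratios are
#' defined at zero-coverage positions. The value used is recorded in the
#' profile metadata.
#'
#' @param profile `position_profile` of kind `"count"`.
#' @param alpha nonnegative pseudocount per position (default 1).
#' @return pseudocounted count profile.
#' @export
add_pseudocounts <- function(profile, alpha = 1) {
  stopifnot(inherits(profile, "position_profile"))
  if (profile$kind != "count")
    stop_validation("add_pseudocounts expects a count profile, got ",
                    profile$kind)
  if (!is_number(alpha) || alpha < 0)
    stop_validation("alpha must be a single nonnegative number")
  meta <- profile$meta
  meta$pseudocount <- alpha
  position_profile(profile$values + alpha, "count", meta)
}

#' Convert counts to fractions of reads
#'
#' `f_i = c_i / sum(c)`; the result sums to one. All-zero input (no reads
#' and no pseudocount) is an error.
#'
#' @param profile `position_profile` of kind `"count"`.
#' @return `position_profile` of kind `"fraction"`.
#' @export
to_fractions <- function(profile) {
  stopifnot(inherits(profile, "position_profile"))
  if (profile$kind != "count")
    stop_validation("to_fractions expects a count profile, got ", profile$kind)
  tot <- sum(profile$values)
  if (tot <= 0)
    stop_validation("count profile sums to zero; add pseudocounts ",
                    "(add_pseudocounts) before normalizing")
  position_profile(profile$values / tot, "fraction", profile$meta)
}

#' Blackman smoothing kernel
#'
#' `w(n) = 0.42 - 0.5 cos(2 pi n / (M-1)) + 0.08 cos(4 pi n / (M-1))`,
#' `n = 0..M-1`, normalized to unit sum. The endpoints are exactly zero.
#'
#' @param m window size (odd, >= 3).
#' @return numeric vector of length `m` summing to 1.
#' @export
blackman_window <- function(m) {
  if (!is_count(m) || m < 3) stop_validation("window must be an integer >= 3")
  n <- seq_len(m) - 1
  w <- 0.42 - 0.5 * cos(2 * pi * n / (m - 1)) + 0.08 * cos(4 * pi * n / (m - 1))
  w <- pmax(w, 0)  # analytically nonnegative; clears fp dust at the endpoints
  w / sum(w)
}

# Same-length convolution with zero padding (exact, no FFT).
conv_same <- function(x, k) {
  n <- length(x); m <- length(k); h <- (m - 1L) %/% 2L
  xp <- c(numeric(h), x, numeric(h))
  drop(stats::embed(xp, m) %*% rev(k))
}

#' Smooth a profile with a Blackman window
#'
#' Linear convolution with the normalized Blackman kernel. At the unit
#' boundaries the kernel is renormalized over in-bounds positions, so a
#' constant profile is a fixed point and no artificial decay is introduced
#' where real signal sits at the edges. An even `window` is adjusted to the
#' next odd value (a symmetric kernel needs odd support); a message reports
#' the adjustment.
#'
#' @param profile `position_profile` or numeric vector.
#' @param window kernel width in nucleotides (default 31; use 51 for ratio
#'   inputs).
#' @return smoothed profile of the same length; kind `"fraction"` becomes
#'   `"smoothed_fraction"`, other kinds are preserved.
#' @examples
#' smooth_blackman(c(0, 0, 1, 0, 0), window = 5)
#' @export
smooth_blackman <- function(profile, window = 31) {
  x <- profile_values(profile)
  if (!is_count(window) || window < 3)
    stop_validation("window must be an integer >= 3")
  if (window %% 2 == 0) {
    message("even window ", window, " adjusted to ", window + 1)
    window <- window + 1
  }
  if (window > length(x))
    stop_validation("window (", window, ") exceeds profile length (",
                    length(x), ")")
  k <- blackman_window(window)
  num <- conv_same(x, k)
  den <- conv_same(rep(1, length(x)), k)
  out <- num / den
  if (!inherits(profile, "position_profile")) return(out)
  kind <- if (profile$kind == "fraction") "smoothed_fraction" else profile$kind
  meta <- profile$meta
  meta$window <- window
  structure(list(values = out, kind = kind, meta = meta),
            class = "position_profile")
}

#' Aggregate replicate profiles (median with a Q2-Q3 band)
#'
#' Per-position median across replicates plus the band between the second
#' and third quartiles (linear-interpolation quantiles, R type 7). For two
#' replicates the median equals their mean.
#'
#' @param profiles list of >= 2 `position_profile`s of equal length and kind.
#' @return object of class `aggregate_profile` with fields `median`,
#'   `band_low` (Q2), `band_high` (Q3), `n_replicates`, `kind`.
#' @export
aggregate_replicates <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L)
    stop_validation("need at least two replicate profiles")
  stopifnot(all(vapply(profiles, inherits, logical(1), "position_profile")))
  kinds <- vapply(profiles, function(p) p$kind, character(1))
  if (length(unique(kinds)) != 1L)
    stop_validation("profiles have mixed kinds: ",
                    paste(unique(kinds), collapse = ", "))
  lens <- vapply(profiles, function(p) length(p$values), integer(1))
  if (length(unique(lens)) != 1L)
    stop_validation("profiles have mismatched lengths: ",
                    paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, lapply(profiles, function(p) p$values))
  q <- apply(mat, 2L, quantile, probs = c(0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = q[1L, ], band_low = q[1L, ], band_high = q[2L, ],
                 n_replicates = nrow(mat), kind = kinds[1L],
                 meta = profiles[[1L]]$meta),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat(sprintf("<aggregate_profile> kind=%s, length=%d, n_replicates=%d\n",
              x$kind, length(x$median), x$n_replicates))
  invisible(x)
}

#' Median track of an aggregate as a position_profile
#' @param aggregate an `aggregate_profile`.
#' @return `position_profile` carrying the per-position median.
#' @export
median_profile <- function(aggregate) {
  stopifnot(inherits(aggregate, "aggregate_profile"))
  structure(list(values = aggregate$median, kind = aggregate$kind,
                 meta = aggregate$meta),
            class = "position_profile")
}
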