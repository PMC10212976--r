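#' Write a profile as a bedGraph track
#'
#' The profile (in unit coordinates, position 0 = 5' end) is mapped to
#' genomic coordinates strand-aware — for a minus-strand unit, unit position
#' 0 is written at genomic `end - 1`. Runs of equal values are merged into
#' single intervals. Values are printed with `%.17g`, so a write/read round
#' trip through [read_track()] is bit-exact.
#'
#' @param profile `position_profile` or numeric vector of unit length.
#' @param unit a [transcription_unit()].
#' @param path output file.
#' @param name track name written in the header line.
#' @return `path`, invisibly.
#' @export
write_track <- function(profile, unit, path, name = NULL) {
  stopifnot(inherits(unit, "transcription_unit"))
  x <- profile_values(profile)
  if (length(x) != unit$length)
    stop_validation("profile length (", length(x),
                    ") does not match unit length (", unit$length, ")")
  # genomic-order values: reverse for minus strand
  g <- if (unit$strand == "+") x else rev(x)
  r <- rle(g)
  ends <- unit$start + cumsum(r$lengths)
  starts <- c(unit$start, ends[-length(ends)])
  if (is.null(name))
    name <- if (inherits(profile, "position_profile")) profile$kind else "track"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  writeLines(sprintf("%s\t%d\t%d\t%.17g", unit$chrom, starts, ends, r$values),
             con)
  invisible(path)
}

#' Read a bedGraph track back into a profile
#'
#' Inverse of [write_track()]: intervals are expanded to one value per unit
#' position and reordered 5' to 3' along the unit.
#'
#' @param path bedGraph file.
#' @param unit a [transcription_unit()].
#' @param kind profile kind to stamp on the result.
#' @return `position_profile`.
#' @export
read_track <- function(path, unit,
                       kind = c("count", "fraction", "smoothed_fraction",
                                "occupancy_time_seconds", "log2_ratio")) {
  kind <- match.arg(kind)
  stopifnot(inherits(unit, "transcription_unit"))
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stop_parse("malformed bedGraph ", path,
                                                ": ", conditionMessage(e)))
  g <- rep(NA_real_, unit$length)
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  sc <- as.numeric(mcols(gr)$score)
  for (i in seq_along(gr)) {
    lo <- max(s0[i], unit$start) - unit$start
    hi <- min(e0[i], unit$end) - unit$start
    if (hi > lo) g[(lo + 1L):hi] <- sc[i]
  }
  if (anyNA(g))
    stop_parse("track ", path, " does not cover the whole unit")
  vals <- if (unit$strand == "+") g else rev(g)
  structure(list(values = vals, kind = kind, meta = list(source = path)),
            class = "position_profile")
}

#' Write a JSON run manifest
#'
#' Records every tunable parameter, the package version, and md5 content
#' hashes of any input files, so a run is fully reproducible from its
#' manifest.
#'
#' @param params named list of parameter values.
#' @param inputs character vector of input file paths (hashed), or NULL.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, inputs = NULL, path) {
  manifest <- list(
    package = "cracpause",
    version = as.character(packageVersion("cracpause")),
    parameters = params)
  if (length(inputs)) {
    h <- tools::md5sum(inputs)
    manifest$input_md5 <- as.list(stats::setNames(unname(h), basename(inputs)))
  }
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
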