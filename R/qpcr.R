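#' ChIP-qPCR measurement
#'
#' Technical-replicate CT values for an immunoprecipitate (IP) and its
#' input (whole-cell extract), with the fold dilutions applied to each
#' before amplification. Defaults mirror the usual setup: IP diluted 20x,
#' input diluted 100x.
#'
#' @param ct_ip,ct_input CT cycles, >= 1 technical replicate each, finite
#'   and positive.
#' @param dilution_ip,dilution_input fold dilutions (> 0).
#' @param amplicon amplicon name.
#' @return object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(ct_ip, ct_input, dilution_ip = 20,
                             dilution_input = 100, amplicon = "amplicon") {
  ct_ip <- as.numeric(ct_ip)
  ct_input <- as.numeric(ct_input)
  if (!length(ct_ip) || !length(ct_input))
    stop_validation("need at least one technical replicate for IP and input")
  if (any(!is.finite(ct_ip)) || any(!is.finite(ct_input)) ||
      any(ct_ip <= 0) || any(ct_input <= 0))
    stop_validation("CT values must be finite and > 0")
  if (!is_number(dilution_ip) || dilution_ip <= 0 ||
      !is_number(dilution_input) || dilution_input <= 0)
    stop_validation("dilutions must be > 0")
  structure(list(ct_ip = ct_ip, ct_input = ct_input,
                 dilution_ip = dilution_ip, dilution_input = dilution_input,
                 amplicon = amplicon),
            class = "qpcr_measurement")
}

#' @export
print.qpcr_measurement <- function(x, ...) {
  cat(sprintf("<qpcr_measurement> %s: IP CT %.3f (n=%d, 1:%g), input CT %.3f (n=%d, 1:%g)\n",
              x$amplicon, mean(x$ct_ip), length(x$ct_ip), x$dilution_ip,
              mean(x$ct_input), length(x$ct_input), x$dilution_input))
  invisible(x)
}

#' ChIP enrichment by the 2^dCT formula
#'
#' `dCT = mean(ct_input) - mean(ct_ip)` (technical replicates summarized by
#' the mean), `abundance = 2^dCT`, multiplied by
#' `dilution_input / dilution_ip` when `apply_dilution_correction` is TRUE.
#' The correction flag is recorded on the result
#' (`attr(, "dilution_corrected")`). Adding a constant to every CT (IP and
#' input alike) leaves the result unchanged.
#'
#' @param m a [qpcr_measurement()].
#' @param apply_dilution_correction default FALSE.
#' @return relative abundance (arbitrary units).
#' @examples
#' m <- qpcr_measurement(ct_ip = 18, ct_input = 20,
#'                       dilution_ip = 20, dilution_input = 100)
#' chip_enrichment(m)                                   # 2^2 = 4
#' chip_enrichment(m, apply_dilution_correction = TRUE) # 4 * 5 = 20
#' @export
chip_enrichment <- function(m, apply_dilution_correction = FALSE) {
  stopifnot(inherits(m, "qpcr_measurement"))
  dct <- mean(m$ct_input) - mean(m$ct_ip)
  ab <- 2^dct
  if (apply_dilution_correction)
    ab <- ab * m$dilution_input / m$dilution_ip
  structure(ab, dilution_corrected = apply_dilution_correction)
}

#' Normalize a ChIP signal to an untagged control
#'
#' @param signal_tagged abundance in the tagged strain.
#' @param signal_untagged abundance in the untagged control (> 0).
#' @return fold over untagged.
#' @export
normalize_to_control <- function(signal_tagged, signal_untagged) {
  if (!is_number(as.numeric(signal_untagged)) || signal_untagged <= 0)
    stop_validation("untagged control signal must be > 0")
  as.numeric(signal_tagged) / as.numeric(signal_untagged)
}

#' Relative expression by the ddCq method
#'
#' `ddCq = (ct_target_test - ct_ref_test) - (ct_target_cal - ct_ref_cal)`;
#' fold change = `2^(-ddCq)`. The reference gene is typically a stable
#' housekeeping transcript (e.g. the alpha-tubulin gene nda2); the
#' calibrator is usually the wild-type sample.
#'
#' @param ct_target_test,ct_target_cal target-gene CTs in test and
#'   calibrator samples (means of technical replicates).
#' @param ct_ref_test,ct_ref_cal reference-gene CTs.
#' @return fold change of the target in test relative to calibrator.
#' @export
relative_expression <- function(ct_target_test, ct_ref_test,
                                ct_target_cal, ct_ref_cal) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(cts))) stop_validation("all CT values must be finite")
  ddcq <- (mean(ct_target_test) - mean(ct_ref_test)) -
    (mean(ct_target_cal) - mean(ct_ref_cal))
  2^(-ddcq)
}

#' Read a CT table and compute enrichment or expression
#'
#' The table (CSV/TSV by extension) must have columns `sample`, `amplicon`,
#' `role` (`IP`/`input` for mode `"chip"`; `target`/`reference` with samples
#' `test`/`calibrator` for mode `"ddcq"`), `dilution`, `ct`.
#'
#' @param path table file.
#' @param mode `"chip"` or `"ddcq"`.
#' @param apply_dilution_correction passed to [chip_enrichment()].
#' @return tidy `data.frame` of results (one row per sample x amplicon for
#'   chip mode; one row per amplicon for ddcq mode).
#' @export
qpcr_table <- function(path, mode = c("chip", "ddcq"),
                       apply_dilution_correction = FALSE) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_parse("CT table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("sample", "amplicon", "role", "dilution", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_parse("CT table missing column(s): ", paste(miss, collapse = ", "))
  if (mode == "chip") {
    keys <- unique(df[, c("sample", "amplicon")])
    out <- lapply(seq_len(nrow(keys)), function(i) {
      sub <- df[df$sample == keys$sample[i] & df$amplicon == keys$amplicon[i], ]
      ip <- sub[sub$role == "IP", ]
      input <- sub[sub$role == "input", ]
      if (!nrow(ip) || !nrow(input))
        stop_validation("sample ", keys$sample[i], " amplicon ",
                        keys$amplicon[i], " lacks IP or input rows")
      m <- qpcr_measurement(ip$ct, input$ct,
                            dilution_ip = ip$dilution[1],
                            dilution_input = input$dilution[1],
                            amplicon = keys$amplicon[i])
      data.frame(sample = keys$sample[i], amplicon = keys$amplicon[i],
                 abundance = as.numeric(
                   chip_enrichment(m, apply_dilution_correction)),
                 dilution_corrected = apply_dilution_correction)
    })
    do.call(rbind, out)
  } else {
    out <- lapply(unique(df$amplicon), function(a) {
      sub <- df[df$amplicon == a, ]
      pick <- function(sample, role) {
        v <- sub$ct[sub$sample == sample & sub$role == role]
        if (!length(v)) stop_validation("ddcq table missing ", sample, "/",
                                        role, " rows for amplicon ", a)
        mean(v)
      }
      data.frame(amplicon = a, fold_change = relative_expression(
        pick("test", "target"), pick("test", "reference"),
        pick("calibrator", "target"), pick("calibrator", "reference")))
    })
    do.call(rbind, out)
  }
}
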