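#' Transcription-unit coordinate frame
#'
#' A transcription unit is a single genomic interval (0-based, half-open)
#' carrying an ordered set of named subregions (for the rDNA unit:
#' 5'ETS, 18S, ITS1, 5.8S, ITS2, 25S, 3'ETS). All per-nucleotide profiles in
#' the package live in *unit coordinates*: position 0 is the unit's 5' end
#' and positions increase 5' to 3' regardless of genomic strand.
#'
#' @param chrom sequence name.
#' @param start,end genomic interval, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param regions optional `data.frame` with columns `name`, `start`, `end`
#'   giving subregions in unit coordinates (0-based half-open).
#' @param name unit name (informational).
#' @return An object of class `transcription_unit` with fields `chrom`,
#'   `start`, `end`, `strand`, `length` and `regions`.
#' @examples
#' unit <- transcription_unit("rDNA", 0, 7800, "+",
#'   regions = data.frame(name = "5ETS", start = 0, end = 1300))
#' unit_length(unit)
#' @export
transcription_unit <- function(chrom, start, end, strand = "+",
                               regions = NULL, name = "unit") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop_validation("chrom must be a non-empty string")
  if (!is_number(start) || !is_number(end) || start < 0 || end <= start)
    stop_validation("need 0 <= start < end; got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-"))
    stop_validation("unknown strand '", strand, "' (must be '+' or '-')")
  len <- as.integer(end - start)
  regions <- validate_regions(regions, len)
  structure(
    list(chrom = chrom, start = as.integer(start), end = as.integer(end),
         strand = strand, length = len, regions = regions, name = name),
    class = "transcription_unit")
}

validate_regions <- function(regions, unit_length) {
  if (is.null(regions) || nrow(regions) == 0L)
    return(data.frame(name = character(), start = integer(), end = integer()))
  if (!all(c("name", "start", "end") %in% names(regions)))
    stop_validation("regions need columns name, start, end")
  regions <- regions[order(regions$start), c("name", "start", "end")]
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  rownames(regions) <- NULL
  bad <- regions$start < 0 | regions$end > unit_length | regions$start >= regions$end
  if (any(bad))
    stop_validation("region '", regions$name[which(bad)[1]],
                    "' falls outside the unit [0, ", unit_length, ") or is empty")
  if (anyDuplicated(regions$name))
    stop_validation("duplicate region name '",
                    regions$name[anyDuplicated(regions$name)], "'")
  if (nrow(regions) > 1L) {
    ovl <- which(regions$start[-1L] < regions$end[-nrow(regions)])
    if (length(ovl))
      stop_validation("regions '", regions$name[ovl[1]], "' and '",
                      regions$name[ovl[1] + 1L], "' overlap")
  }
  regions
}

#' @export
print.transcription_unit <- function(x, ...) {
  cat(sprintf("<transcription_unit> %s %s:%d-%d (%s), length %d nt\n",
              x$name, x$chrom, x$start, x$end, x$strand, x$length))
  if (nrow(x$regions)) {
    cat("regions (unit coordinates):\n")
    print(x$regions)
  }
  invisible(x)
}

#' @rdname transcription_unit
#' @param unit a `transcription_unit`.
#' @export
unit_length <- function(unit) {
  stopifnot(inherits(unit, "transcription_unit"))
  unit$length
}

#' Map unit positions to genomic coordinates
#'
#' Unit position 0 sits at the unit's 5' end: genomic `start` for a
#' plus-strand unit, genomic `end - 1` for a minus-strand unit.
#'
#' @param positions 0-based unit positions.
#' @param unit a `transcription_unit`.
#' @return 0-based genomic positions (single bases).
#' @export
unit_to_genomic <- function(positions, unit) {
  stopifnot(inherits(unit, "transcription_unit"))
  if (any(positions < 0 | positions >= unit$length, na.rm = TRUE))
    stop_validation("unit positions out of [0, ", unit$length, ")")
  if (unit$strand == "+") unit$start + positions else unit$end - 1L - positions
}

#' Read a transcription-unit annotation (BED or GFF3)
#'
#' The file must contain exactly one record spanning all others (the unit)
#' plus zero or more child records (the subregions). GFF3 1-based inclusive
#' coordinates are converted to the package's 0-based half-open convention
#' by `rtracklayer`. Region names are taken from the BED name column or the
#' GFF3 `Name` (falling back to `ID`) attribute.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A [transcription_unit()].
#' @examples
#' gff <- system.file("extdata", "rdna_unit_synthetic.gff3", package = "cracpause")
#' unit <- read_annotation(gff)
#' unit
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_parse("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- if (format == "bed") {
    rtracklayer::import(path, format = "BED")
  } else {
    rtracklayer::import(path, format = "GFF3")
  }
  if (length(gr) == 0L) stop_parse("no records in ", path)
  nm <- if (format == "bed") {
    as.character(mcols(gr)$name)
  } else {
    n <- as.character(mcols(gr)$Name %||% NA_character_)
    id <- as.character(mcols(gr)$ID %||% NA_character_)
    ifelse(is.na(n) | !nzchar(n), id, n)
  }
  nm[is.na(nm)] <- sprintf("record_%d", which(is.na(nm)))
  # 0-based half-open genomic coordinates
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  spans_all <- vapply(seq_along(gr), function(i)
    all(s0 >= s0[i] & e0 <= e0[i]), logical(1))
  if (sum(spans_all) != 1L)
    stop_parse("expected exactly one unit-level record spanning all others in ",
               path, " (found ", sum(spans_all), ")")
  ui <- which(spans_all)
  strand_u <- as.character(GenomicRanges::strand(gr)[ui])
  if (!strand_u %in% c("+", "-"))
    stop_validation("unit record '", nm[ui], "' has unknown strand '", strand_u, "'")
  children <- setdiff(seq_along(gr), ui)
  regions <- NULL
  if (length(children)) {
    same_chrom <- as.character(GenomicRanges::seqnames(gr)[children]) ==
      as.character(GenomicRanges::seqnames(gr)[ui])
    if (!all(same_chrom))
      stop_validation("region '", nm[children[!same_chrom][1]],
                      "' is on a different sequence than the unit")
    # genomic -> unit coordinates, strand-aware
    if (strand_u == "+") {
      rs <- s0[children] - s0[ui]
      re <- e0[children] - s0[ui]
    } else {
      rs <- e0[ui] - e0[children]
      re <- e0[ui] - s0[children]
    }
    regions <- data.frame(name = nm[children], start = rs, end = re)
  }
  transcription_unit(as.character(GenomicRanges::seqnames(gr)[ui]),
                     s0[ui], e0[ui], strand_u, regions = regions, name = nm[ui])
}

#' Packaged synthetic rDNA transcription unit
#'
#' A 7800-nt plus-strand unit whose 5'ETS spans the first 1300 nt. The
#' remaining subregion boundaries are plausible fission-yeast-like sizes and
#' are synthetic (the file name says so): they define a coordinate frame for
#' examples and tests, not a reference annotation.
#'
#' @return A [transcription_unit()] of length 7800 with regions
#'   5ETS, 18S, ITS1, 5.8S, ITS2, 25S, 3ETS.
#' @export
rdna_unit <- function() {
  read_annotation(system.file("extdata", "rdna_unit_synthetic.gff3",
                              package = "cracpause"), format = "gff3")
}
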