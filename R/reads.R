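#' Load aligned reads from BED6, BAM or SAM
#'
#' Reads are returned as a `GRanges` with a numeric `weight` metadata column.
#' Multi-mapped reads are handled per `multimap_policy`:
#' `"keep-all"` (default, every alignment weight 1 — mirrors keeping
#' multi-mappers to cover the multi-copy rDNA), `"primary-only"` (secondary
#' alignments dropped), or `"fractional"` (each alignment weighted 1/NH).
#' For BED input all three policies give weight 1 per record (BED carries no
#' NH/secondary information).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"`, `"bam"` or `"sam"`.
#' @param unit optional [transcription_unit()]; when given, only reads
#'   overlapping the unit's interval on its chromosome are returned.
#' @param multimap_policy see above.
#' @return `GRanges` with `weight` (and `NH` when available).
#' @export
read_alignments <- function(path, format = c("auto", "bed", "bam", "sam"),
                            unit = NULL,
                            multimap_policy = c("keep-all", "primary-only",
                                                "fractional")) {
  format <- match.arg(format)
  multimap_policy <- match.arg(multimap_policy)
  if (!file.exists(path)) stop_parse("alignment file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", bam = "bam", sam = "sam",
                     stop_parse("cannot infer format from extension '.", ext,
                                "'; pass format="))
  }
  gr <- switch(format,
    bed = read_bed6(path),
    bam = read_bam(path, multimap_policy),
    sam = read_bam(Rsamtools::asBam(path,
                     destination = tempfile(fileext = ""),
                     overwrite = TRUE, indexDestination = FALSE),
                   multimap_policy))
  if (!is.null(unit)) {
    stopifnot(inherits(unit, "transcription_unit"))
    keep <- as.character(GenomicRanges::seqnames(gr)) == unit$chrom &
      GenomicRanges::start(gr) <= unit$end &
      GenomicRanges::end(gr) >= unit$start + 1L
    gr <- gr[keep]
  }
  gr
}

read_bed6 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop_parse("malformed BED file ", path,
                                                ": ", conditionMessage(e)))
  mcols(gr)$weight <- rep(1, length(gr))
  gr
}

# Reference-consumed width of a CIGAR string (M, D, N, =, X operations).
cigar_reference_width <- function(cigar) {
  out <- integer(length(cigar))
  parsed <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  for (i in seq_along(parsed)) {
    ops <- parsed[[i]]
    if (!length(ops) || sum(nchar(ops)) != nchar(cigar[i]))
      stop_parse("malformed CIGAR '", cigar[i], "' in record ", i)
    op <- substr(ops, nchar(ops), nchar(ops))
    len <- as.integer(substr(ops, 1L, nchar(ops) - 1L))
    out[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
  }
  out
}

read_bam <- function(path, multimap_policy) {
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "strand", "pos", "cigar", "flag"), tag = "NH")
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  mapped <- !bitwAnd(res$flag, 4L)
  if (multimap_policy == "primary-only")
    mapped <- mapped & !bitwAnd(res$flag, 256L)
  idx <- which(mapped)
  if (!length(idx))
    return(GenomicRanges::GRanges(weight = numeric(0)))
  w <- rep(1, length(idx))
  nh <- res$tag$NH[idx]
  if (multimap_policy == "fractional" && !is.null(nh)) {
    nh_ok <- !is.na(nh) & nh >= 1
    w[nh_ok] <- 1 / nh[nh_ok]
  }
  width <- cigar_reference_width(res$cigar[idx])
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(res$rname[idx]),
    ranges = IRanges(start = res$pos[idx], width = width),
    strand = as.character(res$strand[idx]))
  mcols(gr)$weight <- w
  if (!is.null(nh)) mcols(gr)$NH <- nh
  gr
}

#' Unit-coordinate 3'-end positions of reads
#'
#' The 3' end of a nascent-transcript read marks the polymerase active
#' site. For a plus-strand unit it is the rightmost aligned base, for a
#' minus-strand unit the leftmost. Reads on the wrong chromosome or the
#' strand opposite the unit, or whose 3' end falls outside the unit, map to
#' `NA`. Reads with strand `"*"` are treated as matching the unit strand.
#'
#' @param reads `GRanges` of alignments.
#' @param unit a [transcription_unit()].
#' @return Integer vector of 0-based unit positions (NA = not in unit).
#' @examples
#' unit <- transcription_unit("rDNA", 100, 7900, "+")
#' r <- GenomicRanges::GRanges("rDNA", IRanges::IRanges(151, 200), "+")
#' to_unit_coordinates(r, unit)  # 99
#' @export
to_unit_coordinates <- function(reads, unit) {
  stopifnot(inherits(unit, "transcription_unit"))
  n <- length(reads)
  pos <- rep(NA_integer_, n)
  if (!n) return(pos)
  chrom_ok <- as.character(GenomicRanges::seqnames(reads)) == unit$chrom
  st <- as.character(GenomicRanges::strand(reads))
  strand_ok <- st == unit$strand | st == "*"
  ok <- chrom_ok & strand_ok
  if (unit$strand == "+") {
    # GRanges closed end == 0-based half-open end; 3' end base = end - 1
    p <- GenomicRanges::end(reads) - 1L - unit$start
  } else {
    p <- unit$end - GenomicRanges::start(reads)
  }
  p[!ok | p < 0L | p >= unit$length] <- NA_integer_
  pos[seq_len(n)] <- p
  pos
}

#' Read weights (1 where absent)
#' @param reads `GRanges`.
#' @return numeric vector.
#' @keywords internal
read_weights <- function(reads) {
  w <- mcols(reads)$weight
  if (is.null(w)) rep(1, length(reads)) else as.numeric(w)
}

#' Classify reads into annotation categories
#'
#' Assigns each read to the category it overlaps most (ties broken by the
#' order of `priority`, earlier wins); reads overlapping nothing are
#' "unassigned". Returns the fraction of total read weight per category.
#'
#' @param reads `GRanges` with optional `weight`.
#' @param categories `GRanges` with a `category` metadata column.
#' @param priority character vector of category names defining tie-break and
#'   output order; defaults to order of first appearance.
#' @return named numeric vector of fractions summing to 1 (categories in
#'   priority order, then `"unassigned"`).
#' @export
classify_reads <- function(reads, categories, priority = NULL) {
  if (length(reads) == 0L) stop_validation("empty read set")
  cat_names <- as.character(mcols(categories)$category)
  if (is.null(priority)) priority <- unique(cat_names)
  if (!all(cat_names %in% priority))
    stop_validation("categories missing from priority order: ",
                    paste(setdiff(cat_names, priority), collapse = ", "))
  w <- read_weights(reads)
  hits <- GenomicRanges::findOverlaps(reads, categories, ignore.strand = FALSE)
  assigned <- rep(NA_integer_, length(reads))
  if (length(hits)) {
    qh <- queryHits(hits); sh <- subjectHits(hits)
    ovl <- GenomicRanges::width(GenomicRanges::pintersect(
      GenomicRanges::ranges(reads)[qh], GenomicRanges::ranges(categories)[sh]))
    rank <- match(cat_names[sh], priority)
    ord <- order(qh, -ovl, rank)
    first <- !duplicated(qh[ord])
    assigned[qh[ord][first]] <- sh[ord][first]
  }
  lev <- c(priority, "unassigned")
  grp <- ifelse(is.na(assigned), "unassigned", cat_names[assigned])
  tot <- vapply(lev, function(l) sum(w[grp == l]), numeric(1))
  tot / sum(w)
}

#' Read a sample sheet (TSV or CSV)
#'
#' Columns: `sample_id`, `condition`, `replicate`, `path`, `format`.
#' `(condition, replicate)` pairs must be unique and paths non-empty.
#'
#' @param path file; delimiter inferred from extension (`.csv` = comma,
#'   otherwise tab).
#' @return validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_parse("sample sheet not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate", "path", "format")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_parse("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(df$condition, df$replicate)
  if (anyDuplicated(key))
    stop_validation("duplicate (condition, replicate) pair: ",
                    key[anyDuplicated(key)])
  if (any(!nzchar(df$path)))
    stop_validation("empty path for sample ", df$sample_id[!nzchar(df$path)][1])
  df
}
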