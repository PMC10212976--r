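test_that("BED6 rows parse into weighted reads", {
  bed <- tempfile(fileext = ".bed")
  write_bed6(data.frame(chrom = "rDNA", start = c(150, 10), end = c(200, 20),
                        name = c("r1", "r2"), score = 0,
                        strand = c("+", "+")), bed)
  gr <- read_alignments(bed)
  expect_length(gr, 2L)
  expect_equal(GenomicRanges::start(gr), c(151L, 11L))  # 1-based container
  expect_equal(GenomicRanges::end(gr), c(200L, 20L))
  expect_equal(S4Vectors::mcols(gr)$weight, c(1, 1))
})

test_that("empty alignment files yield empty collections, not errors", {
  bed <- tempfile(fileext = ".bed")
  file.create(bed)
  expect_length(read_alignments(bed), 0L)
})

test_that("unit restriction keeps only overlapping reads", {
  bed <- tempfile(fileext = ".bed")
  write_bed6(data.frame(chrom = c("rDNA", "rDNA", "chrX"),
                        start = c(150, 9000, 150), end = c(200, 9100, 200),
                        name = c("in", "down", "off"), score = 0,
                        strand = "+"), bed)
  unit <- make_unit(length = 7800, start = 100)
  gr <- read_alignments(bed, unit = unit)
  expect_equal(as.character(S4Vectors::mcols(gr)$name), "in")
})

test_that("SAM/BAM reads honor multimap policies (NH fractional weights)", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:rDNA\tLN:10000",
    "r1\t0\trDNA\t151\t255\t50M\t*\t0\t0\t*\t*\tNH:i:4",
    "r1\t256\trDNA\t351\t255\t50M\t*\t0\t0\t*\t*\tNH:i:4",
    "r2\t0\trDNA\t201\t255\t20M10N20M\t*\t0\t0\t*\t*\tNH:i:1",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  all_in <- read_alignments(sam, format = "sam")
  expect_length(all_in, 3L)          # unmapped dropped, secondary kept
  expect_equal(S4Vectors::mcols(all_in)$weight, c(1, 1, 1))

  frac <- read_alignments(sam, format = "sam", multimap_policy = "fractional")
  expect_equal(S4Vectors::mcols(frac)$weight, c(0.25, 0.25, 1))

  prim <- read_alignments(sam, format = "sam", multimap_policy = "primary-only")
  expect_length(prim, 2L)
  # CIGAR with skip: reference width 20 + 10 + 20
  expect_equal(GenomicRanges::end(prim)[2] - GenomicRanges::start(prim)[2] + 1L,
               50L)
})

test_that("3'-end unit positions follow strand conventions", {
  up <- transcription_unit("rDNA", 100, 7900, "+")
  um <- transcription_unit("rDNA", 100, 7900, "-")
  rp <- make_reads(150, 200, "+")
  rm <- make_reads(150, 200, "-")
  expect_equal(to_unit_coordinates(rp, up), 99L)     # 199 - 100
  expect_equal(to_unit_coordinates(rm, um), 7749L)   # 7899 - 150
  # opposite strand and wrong chromosome are excluded, not errors
  expect_true(is.na(to_unit_coordinates(rm, up)))
  expect_true(is.na(to_unit_coordinates(
    make_reads(150, 200, "+", chrom = "chrX"), up)))
  # read entirely downstream of the unit
  expect_true(is.na(to_unit_coordinates(make_reads(9000, 9100, "+"), up)))
})

test_that("simulated minus-strand 3' ends map to unit_end - 1 - p", {
  m <- elongation_model(c(1, 1, 1, 1, 8, 1, 1, 1, 1, 1))
  unit <- transcription_unit("rDNA", 1000, 1010, "-")
  gr <- simulate_reads(m, unit, 200, seed = 3,
                       read_length = read_length_spec("fixed", length = 4))
  p <- to_unit_coordinates(gr, unit)
  expect_false(anyNA(p))
  # 3' end = leftmost base for minus-strand: start0 = unit_end - 1 - p
  expect_equal(GenomicRanges::start(gr) - 1L, 1010L - 1L - p)
})

test_that("reads are classified by maximal overlap with priority tie-break", {
  cats <- GenomicRanges::GRanges("rDNA",
                                 IRanges::IRanges(start = c(1, 101),
                                                  end = c(100, 200)),
                                 "+")
  S4Vectors::mcols(cats)$category <- c("rRNA", "mRNA")
  r <- make_reads(c(10, 20, 30, 120), c(40, 50, 60, 150))
  fr <- classify_reads(r, cats)
  expect_equal(unname(fr), c(0.75, 0.25, 0))
  expect_equal(names(fr), c("rRNA", "mRNA", "unassigned"))
  expect_equal(sum(fr), 1)
  # exact tie in overlap goes to the earlier category in priority order
  tie <- make_reads(90, 110)  # 10 nt in each
  expect_equal(unname(classify_reads(tie, cats))[1], 1)
  expect_equal(unname(classify_reads(tie, cats,
                                     priority = c("mRNA", "rRNA")))[1], 1)
  expect_error(classify_reads(r[0], cats), "empty")
})

test_that("sample sheets validate uniqueness and paths", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = c("a", "b"), condition = c("wt", "wt"),
                   replicate = c(1, 2), path = c("a.bed", "b.bed"),
                   format = "bed")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_sample_sheet(tsv)), 2L)
  df$replicate <- c(1, 1)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_sheet(tsv), "duplicate")
})
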