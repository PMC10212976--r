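#' @keywords internal
"_PACKAGE"

#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom stats median quantile rnorm rgeom cor convolve
#' @importFrom utils read.delim write.table head packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("cracpause_validation_error", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("cracpause_parse_error", "error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == trunc(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a replicate-level seed from a master seed
#'
#' Deterministic, collision-free for small condition/replicate indices, and
#' kept well below `.Machine$integer.max` so it is always a valid R seed.
#'
#' @param master integer master seed.
#' @param condition_index 1-based condition index.
#' @param replicate 1-based replicate index.
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(master, condition_index, replicate) {
  base <- as.integer(master) %% 1000000L
  as.integer(base + 100003L * (condition_index - 1L) + 1009L * replicate)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is_number(seed)) stop_validation("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
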