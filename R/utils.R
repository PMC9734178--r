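## Internal helpers shared across modules.
## Coordinate convention: all intervals in this package are 0-based half-open
## (BED native); conversion to 1-based closed IRanges happens only here.

#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# 0-based half-open data.frame -> GRanges (1-based closed)
.as_granges <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start0 + 1L, end = end0))
}

# absolute summit position (0-based) of each peak
.summit_pos <- function(peaks) {
  if (any(peaks$summit_offset < 0))
    stop("peak(s) without summit offset: ",
         paste(utils::head(peaks$name[peaks$summit_offset < 0], 5), collapse = ", "))
  peaks$start + peaks$summit_offset
}

.stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Area under the ROC curve by the rank statistic
#'
#' Computes AUC as the Mann-Whitney U statistic divided by the number of
#' positive-negative pairs, with ties counted 1/2 (midrank formula). This is
#' algebraically identical to enumerating all pairs.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1, logical, or a factor whose second level is
#'   the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("need both classes to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic per-purpose seed derived from a master seed; kept < 2^31
.derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(offset) %% 1009L
}

# format numbers for deterministic file output
.num_chr <- function(x, digits = 6) {
  out <- formatC(x, digits = digits, format = "g")
  gsub(" ", "", out)
}
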