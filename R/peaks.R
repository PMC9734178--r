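## Summit processing, peak filtering, promoter target assignment and
## paralog-factor redundancy comparisons.

#' Resize peaks to fixed-width regions around their summits
#'
#' Each peak becomes the interval `[summit - flank, summit + flank)` of width
#' `2 * flank` (150 bp at the default), the region conventionally supplied to
#' reproducibility filtering and sequence models. Regions running off the left
#' end of the chromosome are clipped at 0 with a warning.
#'
#' @param peaks peak data.frame (see [read_narrowpeak()]); all peaks must carry
#'   a summit offset.
#' @param flank half-width in bp (default 75).
#' @return peak data.frame with updated `start`/`end`/`summit_offset`.
#' @export
resize_summit_regions <- function(peaks, flank = 75L) {
  flank <- as.integer(flank)
  if (flank <= 0L) stop("flank must be a positive number of bp")
  summit <- .summit_pos(peaks)
  start <- summit - flank
  if (any(start < 0L)) {
    warning(sum(start < 0L), " region(s) clipped at position 0")
    start <- pmax(start, 0L)
  }
  out <- peaks
  out$start <- start
  out$end <- summit + flank
  out$summit_offset <- summit - start
  out
}

#' Filter peaks on IDR and summit signal
#'
#' Keeps peaks that pass both the IDR cut-off and the signal fold-change
#' cut-off (conjunctive), preserving input order. The number removed is
#' reported as a message.
#'
#' @param peaks peak data.frame.
#' @param idr_max maximum IDR (default 0.01); `NULL` disables the IDR filter.
#' @param signal_min minimum signal fold-change (default 0 = no signal filter).
#' @return the surviving peaks (possibly zero rows).
#' @export
filter_peaks <- function(peaks, idr_max = 0.01, signal_min = 0) {
  keep <- rep(TRUE, nrow(peaks))
  if (!is.null(idr_max)) {
    if (is.null(peaks$idr) || anyNA(peaks$idr))
      stop("idr_max given but peaks lack IDR values")
    keep <- keep & peaks$idr <= idr_max
  }
  keep <- keep & peaks$signal_fc >= signal_min
  message(sum(!keep), " of ", nrow(peaks), " peaks removed by filtering")
  peaks[keep, , drop = FALSE]
}

#' Assign peak summits to genes through upstream promoter windows
#'
#' A summit is assigned to a gene when its strand-aware upstream distance to
#' the TSS lies in `[0, window_bp]` (distance 0 = summit exactly at the TSS;
#' downstream summits are never assigned). A summit eligible for several genes
#' goes to the gene at minimal distance, ties broken by lexicographically
#' smallest `gene_id`. One gene may own several summits.
#'
#' @param peaks peak data.frame with summits.
#' @param genes gene data.frame (see [read_gene_table()]).
#' @param window_bp promoter window length in bp (species-specific; e.g. 1500).
#' @return data.frame of assignments: `gene_id`, `peak`, `summit_pos`,
#'   `distance_to_tss`, `signal_fc`, plus `closest` (TRUE on the row holding
#'   each gene's nearest summit).
#' @export
assign_peaks_to_genes <- function(peaks, genes, window_bp) {
  window_bp <- as.integer(window_bp)
  if (window_bp <= 0L) stop("window_bp must be positive")
  summit <- .summit_pos(peaks)
  ## upstream window as an interval on the forward axis:
  ##   + strand: [tss - window, tss]
  ##   - strand: [tss, tss + window]
  win_start <- ifelse(genes$strand == "+", genes$tss - window_bp, genes$tss)
  win_end <- ifelse(genes$strand == "+", genes$tss, genes$tss + window_bp)
  gr_sum <- .as_granges(peaks$chrom, summit, summit + 1L)
  gr_win <- .as_granges(genes$chrom, pmax(win_start, 0L), win_end + 1L)
  ov <- GenomicRanges::findOverlaps(gr_sum, gr_win)
  if (!length(ov)) {
    return(data.frame(gene_id = character(), peak = character(),
                      summit_pos = integer(), distance_to_tss = integer(),
                      signal_fc = numeric(), closest = logical(),
                      stringsAsFactors = FALSE))
  }
  pi <- S4Vectors::queryHits(ov); gi <- S4Vectors::subjectHits(ov)
  dist <- abs(genes$tss[gi] - summit[pi])
  ## one gene per summit: minimal distance, then smallest gene_id
  ord <- order(pi, dist, genes$gene_id[gi])
  pi <- pi[ord]; gi <- gi[ord]; dist <- dist[ord]
  first <- !duplicated(pi)
  pi <- pi[first]; gi <- gi[first]; dist <- dist[first]
  out <- data.frame(gene_id = genes$gene_id[gi], peak = peaks$name[pi],
                    summit_pos = summit[pi], distance_to_tss = dist,
                    signal_fc = peaks$signal_fc[pi], stringsAsFactors = FALSE)
  ord <- order(out$gene_id, out$distance_to_tss, out$peak)
  out <- out[ord, , drop = FALSE]
  out$closest <- !duplicated(out$gene_id)
  rownames(out) <- NULL
  out
}

#' Count overlapping peaks between two peak sets
#'
#' An A peak counts as overlapping when it shares at least `min_overlap` bp
#' with at least one B peak; both directions are counted separately, so the
#' per-side overlap counts may differ.
#'
#' @param setA,setB peak data.frames.
#' @param min_overlap minimum shared bp (default 1).
#' @return list with `a_overlap`, `a_only`, `b_overlap`, `b_only`.
#' @export
peak_overlap <- function(setA, setB, min_overlap = 1L) {
  grA <- .as_granges(setA$chrom, setA$start, setA$end)
  grB <- .as_granges(setB$chrom, setB$start, setB$end)
  ovA <- GenomicRanges::countOverlaps(grA, grB, minoverlap = min_overlap) > 0L
  ovB <- GenomicRanges::countOverlaps(grB, grA, minoverlap = min_overlap) > 0L
  list(a_overlap = sum(ovA), a_only = sum(!ovA),
       b_overlap = sum(ovB), b_only = sum(!ovB))
}

#' Signal correlation of two factors over the union of their summit regions
#'
#' Builds the union of the two sets' summit regions and correlates the two
#' factors' signals across it, the standard check that two paralogous factors
#' share a binding profile.
#'
#' @param peaksA,peaksB peak data.frames with summits.
#' @param signal_lookup function `(chrom, start, end, factor)` returning the
#'   signal of factor `"A"` or `"B"` over a region; defaults to the maximum
#'   `signal_fc` of that factor's peaks overlapping the region.
#' @param flank half-width of the summit regions (default 75).
#' @param log10 correlate on log10 signals (default TRUE).
#' @return list with Pearson `r` and the number of union regions `n`.
#' @export
signal_correlation_in_union <- function(peaksA, peaksB, signal_lookup = NULL,
                                        flank = 75L, log10 = TRUE) {
  regA <- resize_summit_regions(peaksA, flank)
  regB <- resize_summit_regions(peaksB, flank)
  gr <- GenomicRanges::reduce(c(.as_granges(regA$chrom, regA$start, regA$end),
                                .as_granges(regB$chrom, regB$start, regB$end)))
  if (is.null(signal_lookup)) {
    sig_of <- function(peaks) {
      gp <- .as_granges(peaks$chrom, peaks$start, peaks$end)
      ov <- GenomicRanges::findOverlaps(gr, gp)
      s <- rep(NA_real_, length(gr))
      if (length(ov)) {
        agg <- tapply(peaks$signal_fc[S4Vectors::subjectHits(ov)],
                      S4Vectors::queryHits(ov), max)
        s[as.integer(names(agg))] <- agg
      }
      s
    }
    sa <- sig_of(peaksA); sb <- sig_of(peaksB)
  } else {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    s0 <- GenomicRanges::start(gr) - 1L; e0 <- GenomicRanges::end(gr)
    sa <- mapply(signal_lookup, chrom, s0, e0, MoreArgs = list(factor = "A"))
    sb <- mapply(signal_lookup, chrom, s0, e0, MoreArgs = list(factor = "B"))
  }
  ok <- !is.na(sa) & !is.na(sb)
  if (sum(ok) < 3L) stop("fewer than 3 union regions with signal for both factors")
  x <- sa[ok]; y <- sb[ok]
  if (log10) { x <- log10(x); y <- log10(y) }
  list(r = stats::cor(x, y), n = sum(ok))
}
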