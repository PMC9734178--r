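## Motif scanning: IUPAC degenerate consensus matching, log-odds PWM scoring,
## and classification of hits into bound / unbound-background sets.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.check_iupac <- function(consensus) {
  sym <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(sym, names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC symbol(s): ", paste(unique(bad), collapse = ", "))
  sym
}

.empty_hits <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(), klass = character(),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for a degenerate IUPAC consensus
#'
#' Reports every exact degenerate match on the plus strand and, when
#' `both_strands`, every window matching the reverse complement of the
#' consensus, in plus-strand coordinates (0-based half-open). Overlapping and
#' palindromic hits are all reported.
#'
#' @param seq a character string or [Biostrings::DNAString] (or a named
#'   character vector / `DNAStringSet` for multiple sequences).
#' @param consensus IUPAC consensus string, e.g. `"RGATTYY"`.
#' @param both_strands scan the minus strand too (default TRUE).
#' @param seq_id id used in the output when `seq` is a single unnamed sequence.
#' @return data.frame of hits: `seq_id`, `start`, `end`, `strand`, `score`
#'   (= consensus length for exact degenerate matches), `klass` (`NA` until
#'   [classify_motif_sites()]).
#' @export
scan_iupac <- function(seq, consensus, both_strands = TRUE, seq_id = "seq") {
  .check_iupac(consensus)
  seqs <- if (inherits(seq, "DNAStringSet")) seq
          else if (inherits(seq, "DNAString")) stats::setNames(Biostrings::DNAStringSet(seq), seq_id)
          else {
    ss <- Biostrings::DNAStringSet(unlist(seq))
    if (is.null(names(ss)) || any(!nzchar(names(ss))))
      names(ss) <- if (length(ss) == 1L) seq_id else paste0(seq_id, seq_along(ss))
    ss
  }
  pat <- Biostrings::DNAString(toupper(consensus))
  rcpat <- Biostrings::reverseComplement(pat)
  L <- length(pat)
  out <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    res <- list()
    if (length(s) >= L) {
      mp <- Biostrings::matchPattern(pat, s, fixed = FALSE)
      if (length(mp))
        res[["+"]] <- data.frame(seq_id = names(seqs)[i],
                                 start = Biostrings::start(mp) - 1L,
                                 end = Biostrings::end(mp), strand = "+",
                                 score = L, klass = NA_character_,
                                 stringsAsFactors = FALSE)
      if (both_strands) {
        mm <- Biostrings::matchPattern(rcpat, s, fixed = FALSE)
        if (length(mm))
          res[["-"]] <- data.frame(seq_id = names(seqs)[i],
                                   start = Biostrings::start(mm) - 1L,
                                   end = Biostrings::end(mm), strand = "-",
                                   score = L, klass = NA_character_,
                                   stringsAsFactors = FALSE)
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  })
  out <- do.call(rbind, c(out, list(.empty_hits())))
  out <- out[order(match(out$seq_id, names(seqs)), out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score sequence windows against a probability PWM
#'
#' Windows are scored as the sum over positions of
#' `log2(p(base) / 0.25)` after adding a small pseudocount to the matrix
#' (uniform background). Hits are windows scoring strictly above `score_min`,
#' on both strands (minus-strand windows are scored against the
#' reverse-complemented matrix and reported in plus coordinates).
#'
#' @param seq character string / `DNAString` (or named vector / `DNAStringSet`).
#' @param pwm 4 x L probability matrix with rows A, C, G, T; columns must sum
#'   to 1.
#' @param score_min score threshold (default 6, the conventional cut-off of
#'   motif-search tools; the scale here is log2 bits).
#' @param both_strands scan both strands (default TRUE).
#' @param pseudocount added before the log (default 1e-3).
#' @param seq_id id for a single unnamed input sequence.
#' @return hits data.frame as in [scan_iupac()], `score` = log2-odds.
#' @export
score_pwm <- function(seq, pwm, score_min = 6, both_strands = TRUE,
                      pseudocount = 1e-3, seq_id = "seq") {
  pwm <- as.matrix(pwm)
  if (nrow(pwm) != 4L) stop("pwm must have 4 rows (A, C, G, T)")
  if (any(abs(colSums(pwm) - 1) > 1e-6))
    stop("pwm column(s) do not sum to 1: ",
         paste(which(abs(colSums(pwm) - 1) > 1e-6), collapse = ", "))
  rownames(pwm) <- c("A", "C", "G", "T")
  q <- sweep(pwm + pseudocount, 2L, colSums(pwm + pseudocount), "/")
  lod <- log2(q / 0.25)
  L <- ncol(lod)
  seqs <- if (inherits(seq, "DNAStringSet")) seq
          else if (inherits(seq, "DNAString")) stats::setNames(Biostrings::DNAStringSet(seq), seq_id)
          else {
    ss <- Biostrings::DNAStringSet(unlist(seq))
    if (is.null(names(ss)) || any(!nzchar(names(ss))))
      names(ss) <- if (length(ss) == 1L) seq_id else paste0(seq_id, seq_along(ss))
    ss
  }
  score_strand <- function(codes, mat) {
    n <- length(codes) - L + 1L
    if (n < 1L) return(numeric())
    sc <- numeric(n)
    for (j in seq_len(L)) {
      b <- codes[j:(j + n - 1L)]
      col <- mat[, j]
      sc <- sc + ifelse(is.na(b), -Inf, col[b])
    }
    sc
  }
  rc_lod <- lod[4:1, L:1, drop = FALSE]   # reverse complement of the matrix
  out <- lapply(seq_along(seqs), function(i) {
    codes <- match(strsplit(as.character(seqs[[i]]), "")[[1]], c("A", "C", "G", "T"))
    res <- list()
    sc <- score_strand(codes, lod)
    hit <- which(sc > score_min)
    if (length(hit))
      res[["+"]] <- data.frame(seq_id = names(seqs)[i], start = hit - 1L,
                               end = hit - 1L + L, strand = "+",
                               score = sc[hit], klass = NA_character_,
                               stringsAsFactors = FALSE)
    if (both_strands) {
      sc <- score_strand(codes, rc_lod)
      hit <- which(sc > score_min)
      if (length(hit))
        res[["-"]] <- data.frame(seq_id = names(seqs)[i], start = hit - 1L,
                                 end = hit - 1L + L, strand = "-",
                                 score = sc[hit], klass = NA_character_,
                                 stringsAsFactors = FALSE)
    }
    if (length(res)) do.call(rbind, res) else NULL
  })
  out <- do.call(rbind, c(out, list(.empty_hits())))
  out <- out[order(match(out$seq_id, names(seqs)), out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify motif hits into bound / unbound-background / excluded
#'
#' A hit overlapping (>= 1 bp) a TF ChIP-seq peak is `bound`; a hit inside an
#' open-chromatin region that overlaps no TF peak is `unbound_background`
#' (open chromatin without TF signal, the standard background for selection
#' contrasts); everything else is `excluded`. Overlap is against the full peak
#' intervals; hit `seq_id` must be the chromosome name.
#'
#' @param hits hits data.frame from [scan_iupac()] / [score_pwm()].
#' @param tf_peaks TF peak data.frame.
#' @param open_chromatin open-chromatin (e.g. ATAC-seq) peak data.frame.
#' @return `hits` with `klass` filled in.
#' @export
classify_motif_sites <- function(hits, tf_peaks, open_chromatin) {
  if (!nrow(hits)) { hits$klass <- character(0); return(hits) }
  gh <- .as_granges(hits$seq_id, hits$start, hits$end)
  in_tf <- GenomicRanges::countOverlaps(
    gh, .as_granges(tf_peaks$chrom, tf_peaks$start, tf_peaks$end)) > 0L
  in_oc <- GenomicRanges::countOverlaps(
    gh, .as_granges(open_chromatin$chrom, open_chromatin$start, open_chromatin$end)) > 0L
  hits$klass <- ifelse(in_tf, "bound",
                       ifelse(in_oc, "unbound_background", "excluded"))
  hits
}
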