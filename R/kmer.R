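## Bag-of-k-mers classifier separating TF-bound summit sequence from
## open-chromatin background, with top-k-mer reporting.

#' Extract fixed-width sequence windows centered at peak summits
#'
#' Windows span `[summit - width/2, summit + width/2)`. Windows containing
#' `N` or running past a contig end are dropped, with the counts reported as
#' a warning.
#'
#' @param peaks peak data.frame with summits.
#' @param width even window width in bp (conventionally 150 or 300).
#' @param fasta genome as a named [Biostrings::DNAStringSet] (names =
#'   chromosomes) or a FASTA file path.
#' @return named character vector of sequences (names = peak names).
#' @export
extract_windows <- function(peaks, width, fasta) {
  width <- as.integer(width)
  if (width %% 2L != 0L || width <= 0L) stop("width must be a positive even number")
  genome <- if (inherits(fasta, "DNAStringSet")) fasta
            else Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  summit <- .summit_pos(peaks)
  start0 <- summit - width %/% 2L
  end0 <- summit + width %/% 2L
  seqs <- character(nrow(peaks))
  drop_oob <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    chr <- peaks$chrom[i]
    if (!chr %in% names(genome) || start0[i] < 0L ||
        end0[i] > length(genome[[chr]])) {
      drop_oob[i] <- TRUE
      next
    }
    seqs[i] <- as.character(Biostrings::subseq(genome[[chr]],
                                               start = start0[i] + 1L,
                                               end = end0[i]))
  }
  drop_n <- !drop_oob & grepl("N", seqs, fixed = TRUE)
  if (any(drop_oob) || any(drop_n))
    warning(sum(drop_oob), " window(s) beyond contig bounds and ",
            sum(drop_n), " N-containing window(s) dropped")
  keep <- !drop_oob & !drop_n
  stats::setNames(seqs[keep], peaks$name[keep])
}

#' Build a balanced bound / background sequence dataset
#'
#' Negatives are open-chromatin summit windows; regions overlapping weak TF
#' peaks (e.g. the IDR-0.05 set) are removed first, and an equal number of
#' the remainder is sampled to match the positives.
#'
#' @param pos_seqs character vector of positive (bound) sequences.
#' @param bg_peaks open-chromatin peak data.frame with summits.
#' @param fasta genome (`DNAStringSet` or path).
#' @param weak_peaks optional peak data.frame; background regions overlapping
#'   any of them are excluded.
#' @param width window width (must match the positives' length).
#' @param seed RNG seed for the background sample.
#' @return data.frame with `seq` and `label` (1 = bound, 0 = background).
#' @export
build_balanced_dataset <- function(pos_seqs, bg_peaks, fasta,
                                   weak_peaks = NULL, width = NULL,
                                   seed = 1L) {
  if (is.null(width)) width <- unique(nchar(pos_seqs))
  if (length(width) != 1L) stop("positive sequences have mixed lengths")
  if (!is.null(weak_peaks) && nrow(weak_peaks)) {
    reg <- resize_summit_regions(bg_peaks, width %/% 2L)
    bad <- GenomicRanges::countOverlaps(
      .as_granges(reg$chrom, reg$start, reg$end),
      .as_granges(weak_peaks$chrom, weak_peaks$start, weak_peaks$end)) > 0L
    bg_peaks <- bg_peaks[!bad, , drop = FALSE]
  }
  bg_seqs <- suppressWarnings(extract_windows(bg_peaks, width, fasta))
  if (length(bg_seqs) < length(pos_seqs))
    stop("insufficient background: ", length(bg_seqs), " regions for ",
         length(pos_seqs), " positives")
  set.seed(.derive_seed(seed, 101L))
  neg <- bg_seqs[sample.int(length(bg_seqs), length(pos_seqs))]
  data.frame(seq = c(unname(pos_seqs), unname(neg)),
             label = rep(c(1L, 0L), c(length(pos_seqs), length(neg))),
             stringsAsFactors = FALSE)
}

# canonical (strand-collapsed) k-mer count matrix: sequences x canonical k-mers
.count_canonical_kmers <- function(seqs, k) {
  mat <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                              width = k)
  kmers <- colnames(mat)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canon <- pmin(kmers, rc)
  t(rowsum(t(mat), group = canon))
}

#' Train a bag-of-k-mers classifier
#'
#' Features are counts of canonical k-mers (each k-mer merged with its
#' reverse complement, since ChIP fragments are unstranded). The classifier
#' is a sparse (L1-penalised) logistic regression: with thousands of k-mer
#' features and a handful of informative ones, the lasso recovers the
#' informative k-mers where a pure ridge fit lets accumulated noise-feature
#' variance swamp them. Performance is measured on a held-out test split and
#' k-mers are ranked by model weight.
#'
#' @param dataset data.frame with `seq` and binary `label`
#'   ([build_balanced_dataset()] output).
#' @param k k-mer length (default 7).
#' @param test_frac held-out fraction (default 0.2, i.e. an 80/20 split).
#' @param seed RNG seed for the split.
#' @param n_top number of top-ranked k-mers to report (default 10).
#' @param lambda penalty strength passed to [glmnet::glmnet()] (default 0.01).
#' @param alpha elastic-net mixing parameter (default 1 = lasso).
#' @return object of class `kmer_model`: list with `k`, `weights` (named
#'   vector over canonical k-mers), `auc`, `acc`, `top_kmers`, `train_idx`,
#'   `test_idx`, `seed`.
#' @export
train_bag_of_kmers <- function(dataset, k = 7L, test_frac = 0.2, seed = 1L,
                               n_top = 10L, lambda = 0.01, alpha = 1) {
  if (length(unique(dataset$label)) < 2L)
    stop("dataset contains a single class")
  if (k > min(nchar(dataset$seq))) stop("k exceeds the shortest sequence")
  X <- .count_canonical_kmers(dataset$seq, k)
  y <- dataset$label
  n <- nrow(X)
  set.seed(.derive_seed(seed, 202L))
  test_idx <- sort(sample.int(n, max(1L, round(test_frac * n))))
  train_idx <- setdiff(seq_len(n), test_idx)
  Xtr <- X[train_idx, , drop = FALSE]
  if (all(colSums(abs(sweep(Xtr, 2L, Xtr[1L, ], "-"))) == 0)) {
    ## all features constant on the training set: no usable signal
    w <- stats::setNames(rep(0, ncol(X)), colnames(X))
    pred <- rep(0.5, length(test_idx))
  } else {
    fit <- glmnet::glmnet(Xtr, y[train_idx],
                          family = "binomial", alpha = alpha, lambda = lambda,
                          standardize = TRUE)
    w <- as.numeric(fit$beta)
    names(w) <- rownames(fit$beta)
    pred <- as.numeric(stats::predict(fit, X[test_idx, , drop = FALSE],
                                      type = "response"))
  }
  auc <- auc_rank(pred, y[test_idx])
  acc <- mean((pred > 0.5) == (y[test_idx] == 1L))
  ord <- order(-w, names(w))
  structure(list(k = as.integer(k), weights = w, auc = auc, acc = acc,
                 top_kmers = names(w)[ord][seq_len(min(n_top, length(w)))],
                 train_idx = train_idx, test_idx = test_idx, seed = seed),
            class = "kmer_model")
}

#' @export
print.kmer_model <- function(x, ...) {
  cat("Bag-of-k-mers classifier (k =", x$k, ")\n")
  cat("  held-out AUC:", round(x$auc, 3), " ACC:", round(x$acc, 3), "\n")
  cat("  top k-mers:", paste(utils::head(x$top_kmers, 5), collapse = " "), "\n")
  invisible(x)
}
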