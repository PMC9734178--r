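# Independent brute-force oracles, deliberately implemented by different
# routes than the package code they check.

# IUPAC scan by regex expansion with overlapping matches (lookahead)
oracle_iupac_scan <- function(seq, consensus) {
  expand <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
              S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
              D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  sym <- strsplit(consensus, "")[[1]]
  rc_sym <- rev(unname(comp[sym]))
  rx <- function(symbols)
    paste0("(?=", paste(expand[symbols], collapse = ""), ")")
  starts <- function(pattern) {
    m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m) - 1L
  }
  L <- length(sym)
  rbind(
    if (length(s <- starts(rx(sym))))
      data.frame(start = s, end = s + L, strand = "+"),
    if (length(s <- starts(rx(rc_sym))))
      data.frame(start = s, end = s + L, strand = "-"))
}

# quadratic brute force over all (summit, gene) pairs
oracle_assign <- function(peaks, genes, window_bp) {
  summit <- peaks$start + peaks$summit_offset
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    best_gene <- NA_character_; best_d <- Inf
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      d <- if (genes$strand[j] == "+") genes$tss[j] - summit[i]
           else summit[i] - genes$tss[j]
      if (d < 0 || d > window_bp) next
      if (d < best_d || (d == best_d && genes$gene_id[j] < best_gene)) {
        best_d <- d; best_gene <- genes$gene_id[j]
      }
    }
    if (!is.na(best_gene))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = best_gene, peak = peaks$name[i], distance = best_d)
  }
  if (!length(rows)) return(data.frame(gene_id = character(),
                                       peak = character(),
                                       distance = numeric()))
  do.call(rbind, rows)
}

# AUC by explicit pair enumeration
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Kendall tau-b by explicit pair enumeration with tie bookkeeping
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# naive sliding-window canonical k-mer counter for one sequence
oracle_kmer_counts <- function(seq, k) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  counts <- list()
  for (i in seq_len(nchar(seq) - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    canon <- min(w, revcomp(w))
    counts[[canon]] <- (if (is.null(counts[[canon]])) 0 else counts[[canon]]) + 1
  }
  unlist(counts)
}

oracle_revcomp <- function(kmers) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(kmers, function(s)
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = ""), "",
    USE.NAMES = FALSE)
}
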