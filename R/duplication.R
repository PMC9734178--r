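## Concordance of TF binding and expression between duplicated genes:
## binding-retention classification, Kendall rank correlation of duplicate
## signals, and retention-stratified expression correlation.

#' Classify binding retention of duplicate gene pairs
#'
#' Each pair is labeled by how many of its two genes remain TF targets:
#' `both`, `single` or `none`. Genes occurring in several pairs are allowed
#' (reported via message).
#'
#' @param pairs data.frame with `gene_a`, `gene_b` (and any other columns,
#'   e.g. `origin`).
#' @param targets character vector of target gene ids.
#' @return `pairs` with a `retention` column.
#' @export
classify_retention <- function(pairs, targets) {
  .stopifnot_cols(pairs, c("gene_a", "gene_b"), "pairs")
  a <- pairs$gene_a %in% targets
  b <- pairs$gene_b %in% targets
  pairs$retention <- ifelse(a & b, "both", ifelse(a | b, "single", "none"))
  n_multi <- sum(duplicated(c(pairs$gene_a, pairs$gene_b)))
  if (n_multi) message(n_multi, " gene(s) occur in more than one pair")
  pairs
}

# tie-corrected Kendall tau-b p-value helpers
.tau_b_p_normal <- function(x, y) {
  n <- length(x)
  cnt <- function(v) { t <- table(v); t[t > 1L] }
  tx <- as.numeric(cnt(x)); ty <- as.numeric(cnt(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  r <- rank(x); s <- rank(y)
  S <- 0
  for (i in seq_len(n - 1L)) {
    dx <- sign(x[(i + 1L):n] - x[i]); dy <- sign(y[(i + 1L):n] - y[i])
    S <- S + sum(dx * dy)
  }
  z <- S / sqrt(var_s)
  list(S = S, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Kendall rank correlation of duplicate-pair binding signals
#'
#' Tie-corrected tau-b with a two-sided p-value from the normal
#' approximation; for n <= 8 without ties the exact permutation null is
#' enumerated instead.
#'
#' @param pairs data.frame with `signal_a` and `signal_b`.
#' @return list with `tau`, `p`, `n`.
#' @export
signal_concordance <- function(pairs) {
  x <- pairs$signal_a; y <- pairs$signal_b
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 pairs with both signals")
  tau <- stats::cor(x, y, method = "kendall")   # tau-b under ties
  no_ties <- !anyDuplicated(x) && !anyDuplicated(y)
  if (n <= 8L && no_ties) {
    perms <- .permutations(n)
    obs <- abs(tau)
    taus <- apply(perms, 1L, function(pp) stats::cor(x, y[pp], method = "kendall"))
    p <- mean(abs(taus) >= obs - 1e-12)
  } else {
    p <- .tau_b_p_normal(x, y)$p
  }
  list(tau = tau, p = p, n = n)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i)) }))
}

#' Expression correlation of duplicate pairs, stratified by retention
#'
#' Computes each pair's Pearson correlation of expression across tissues,
#' groups pairs by binding-retention class, and compares classes with a
#' one-sided Welch t-test of H1: mean r(both) > mean r(none); both-vs-single
#' is reported alongside. Pairs with a constant expression vector are dropped
#' (message).
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `retention`
#'   ([classify_retention()] output).
#' @param expr_matrix numeric matrix, genes x tissues (>= 2 tissues),
#'   rownames = gene ids.
#' @return list: `per_pair` (pairs + `expr_corr`), `class_means`,
#'   `t_both_vs_none`, `p_both_vs_none`, `t_both_vs_single`,
#'   `p_both_vs_single`.
#' @export
expression_correlation_by_retention <- function(pairs, expr_matrix) {
  if (ncol(expr_matrix) < 2L) stop("need >= 2 tissues")
  r <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!(ga %in% rownames(expr_matrix)) || !(gb %in% rownames(expr_matrix)))
      next
    ea <- expr_matrix[ga, ]; eb <- expr_matrix[gb, ]
    if (stats::sd(ea) == 0 || stats::sd(eb) == 0) next
    r[i] <- stats::cor(ea, eb)
  }
  n_drop <- sum(is.na(r))
  if (n_drop) message(n_drop, " pair(s) dropped (missing or constant expression)")
  pairs$expr_corr <- r
  per_class <- split(r[!is.na(r)], pairs$retention[!is.na(r)])
  need <- function(cls) if (is.null(per_class[[cls]]) || length(per_class[[cls]]) < 2L)
    stop("fewer than 2 usable pairs in class '", cls, "'") else per_class[[cls]]
  both <- need("both"); none <- need("none"); single <- need("single")
  t_bn <- stats::t.test(both, none, alternative = "greater", var.equal = FALSE)
  t_bs <- stats::t.test(both, single, alternative = "greater", var.equal = FALSE)
  list(per_pair = pairs,
       class_means = vapply(per_class, mean, 0),
       t_both_vs_none = unname(t_bn$statistic), p_both_vs_none = t_bn$p.value,
       t_both_vs_single = unname(t_bs$statistic), p_both_vs_single = t_bs$p.value)
}
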