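test_that("retention classes follow pair membership in the target set", {
  pairs <- data.frame(gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
                      stringsAsFactors = FALSE)
  out <- classify_retention(pairs, targets = c("a", "b", "c"))
  expect_equal(out$retention, c("both", "single", "none"))
  # classes partition the pair set
  expect_equal(sum(table(out$retention)), nrow(pairs))
  expect_message(classify_retention(rbind(pairs, pairs[1, ]), "a"),
                 "more than one pair")
})

test_that("Kendall tau-b matches pair enumeration, including ties", {
  expect_equal(signal_concordance(data.frame(signal_a = c(1, 2, 3),
                                             signal_b = c(1, 3, 2)))$tau,
               1 / 3)
  expect_equal(signal_concordance(data.frame(signal_a = 1:5,
                                             signal_b = 1:5))$tau, 1)
  expect_equal(signal_concordance(data.frame(signal_a = 1:5,
                                             signal_b = 5:1))$tau, -1)
  set.seed(41)
  for (rep in 1:4) {
    n <- sample(10:50, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- x + sample(-2:2, n, replace = TRUE)
    out <- signal_concordance(data.frame(signal_a = x, signal_b = y))
    expect_equal(out$tau, oracle_tau_b(x, y))
    expect_true(out$p >= 0 && out$p <= 1)
  }
  expect_error(signal_concordance(data.frame(signal_a = 1:2,
                                             signal_b = 2:1)), ">= 3")
})

test_that("small-sample Kendall p comes from exact enumeration", {
  out <- signal_concordance(data.frame(signal_a = c(0.3, 1.2, 2.7, 3.1, 4.9),
                                       signal_b = c(0.1, 1.7, 2.2, 3.9, 4.4)))
  # perfectly concordant n = 5: two-sided exact p = 2/5!
  expect_equal(out$tau, 1)
  expect_equal(out$p, 2 / 120)
  # agrees with cor.test's exact Kendall p
  ref <- stats::cor.test(c(0.3, 1.2, 2.7, 3.1, 4.9),
                         c(0.1, 1.7, 2.2, 3.9, 4.4), method = "kendall")
  expect_equal(out$p, ref$p.value)
})

test_that("expression correlation is stratified by retention with a one-sided Welch test", {
  set.seed(42)
  n_t <- 6L
  mk <- function(rho, i) {
    za <- rnorm(n_t); zb <- rho * za + sqrt(1 - rho^2) * rnorm(n_t)
    m <- rbind(za, zb)
    rownames(m) <- paste0(c("a", "b"), i)
    m
  }
  rhos <- c(rep(0.95, 10), rep(0.5, 10), rep(0, 10))
  em <- do.call(rbind, lapply(seq_along(rhos), function(i) mk(rhos[i], i)))
  pairs <- data.frame(gene_a = paste0("a", seq_along(rhos)),
                      gene_b = paste0("b", seq_along(rhos)),
                      retention = rep(c("both", "single", "none"), each = 10),
                      stringsAsFactors = FALSE)
  out <- expression_correlation_by_retention(pairs, em)
  expect_equal(out$class_means[["both"]],
               mean(out$per_pair$expr_corr[1:10]))
  expect_gt(out$class_means[["both"]], out$class_means[["none"]])
  expect_lt(out$p_both_vs_none, 0.05)
  # a pair with identical profiles has r = 1
  em2 <- rbind(x1 = 1:6, y1 = 1:6, x2 = c(2, 1, 3, 6, 4, 5),
               y2 = c(5, 4, 2, 1, 3, 6), x3 = rnorm(6), y3 = rnorm(6),
               x4 = rnorm(6), y4 = rnorm(6), x5 = rnorm(6), y5 = rnorm(6),
               x6 = rnorm(6), y6 = rnorm(6))
  pairs2 <- data.frame(gene_a = paste0("x", 1:6), gene_b = paste0("y", 1:6),
                       retention = c("both", "both", "single", "single",
                                     "none", "single"),
                       stringsAsFactors = FALSE)
  pairs2 <- rbind(pairs2,
                  data.frame(gene_a = "x1", gene_b = "y1", retention = "none"))
  out2 <- expression_correlation_by_retention(pairs2, em2)
  expect_equal(out2$per_pair$expr_corr[1], 1)
  # constant profiles are dropped with a message
  em3 <- em2; em3["x3", ] <- 1
  expect_message(expression_correlation_by_retention(pairs2, em3), "dropped")
})

test_that("the one-sided t-test calibrates on null duplicate cohorts", {
  set.seed(43)
  n_pairs <- 36L; n_t <- 8L
  pairs <- data.frame(gene_a = paste0("a", 1:n_pairs),
                      gene_b = paste0("b", 1:n_pairs),
                      retention = rep(c("both", "single", "none"),
                                      each = n_pairs / 3L),
                      stringsAsFactors = FALSE)
  rej <- replicate(200, {
    em <- matrix(rnorm(2L * n_pairs * n_t), nrow = 2L * n_pairs)
    rownames(em) <- c(rbind(pairs$gene_a, pairs$gene_b))
    expression_correlation_by_retention(pairs, em)$p_both_vs_none < 0.05
  })
  expect_lt(mean(rej), 0.12)
  expect_gt(mean(rej), 0.005)
})

test_that("retention ordering emerges on the planted cohort", {
  co <- small_cohort()
  focal <- co$config$species[[1]]
  pairs <- utils::read.delim(co$paths$duplicate_pairs)
  pairs <- suppressMessages(
    classify_retention(pairs, co$truth$targets_by_species[[focal]]))
  # planted retention recovered exactly
  expect_equal(pairs$retention, co$truth$pair_retention)
  tis <- utils::read.delim(co$paths$tissue_expression, check.names = FALSE)
  em <- as.matrix(tis[, -1]); rownames(em) <- tis[[1]]
  out <- suppressMessages(expression_correlation_by_retention(pairs, em))
  cm <- out$class_means
  expect_true(cm[["both"]] > cm[["single"]] && cm[["single"]] > cm[["none"]])
  expect_lt(out$p_both_vs_none, 0.05)
})
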