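deg_table <- function(n_deg, n_down, n_other = 0L) {
  n <- n_deg + n_other
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             is_deg = rep(c(TRUE, FALSE), c(n_deg, n_other)),
             is_down = rep(c(TRUE, FALSE, FALSE), c(n_down, n_deg - n_down,
                                                    n_other)),
             stringsAsFactors = FALSE)
}

test_that("DEG overlap summary reports the down-regulated percentage", {
  tab <- deg_table(266L, 202L, 100L)
  out <- summarize_deg_overlap(tab$gene_id, tab)
  expect_equal(out$pct_down, 75.94)
  expect_equal(out$n_target_deg, 266L)
  # all target DEGs down
  tab2 <- deg_table(10L, 10L)
  expect_equal(summarize_deg_overlap(tab2$gene_id, tab2)$pct_down, 100)
  # zero target DEGs: undefined percentage, zero counts
  out0 <- summarize_deg_overlap(character(), tab)
  expect_true(is.na(out0$pct_down))
  expect_equal(out0$n_target_deg, 0L)
  # counts invariant to row order
  perm <- tab[sample.int(nrow(tab)), ]
  expect_equal(summarize_deg_overlap(tab$gene_id, perm), out)
  # inconsistent and duplicated rows are rejected
  bad <- tab; bad$is_down[300] <- TRUE
  expect_error(summarize_deg_overlap(tab$gene_id, bad), "non-DEG")
  expect_error(summarize_deg_overlap(tab$gene_id, rbind(tab, tab[1, ])),
               "duplicated")
})

test_that("DEG fraction by conservation group orders and handles empty groups", {
  cons <- list(levels = stats::setNames(c(1L, 1L, 2L, 2L, 4L),
                                        sprintf("g%d", 1:5)),
               S = 4L)
  deg <- data.frame(gene_id = sprintf("g%d", 1:5),
                    is_deg = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  out <- deg_rate_by_conservation(cons, deg)
  expect_equal(out$fraction, c(0.5, 1, NA, 1))
  expect_equal(out$n, c(2L, 2L, 0L, 1L))
})

test_that("binding strength by group uses the tie-corrected Kruskal-Wallis H", {
  asn <- data.frame(gene_id = sprintf("g%d", 1:6), peak = sprintf("p%d", 1:6),
                    summit_pos = 1:6, distance_to_tss = 100L,
                    signal_fc = 10^c(1, 2, 3, 4, 5, 6), closest = TRUE,
                    stringsAsFactors = FALSE)
  cons <- list(levels = stats::setNames(rep(1:2, each = 3L),
                                        sprintf("g%d", 1:6)), S = 2L)
  out <- binding_strength_by_group(asn, cons)
  expect_equal(out$H, 3.857, tolerance = 1e-3)  # ranks (1,2,3) vs (4,5,6)
  expect_equal(out$df, 1L)
  # all observations equal: H = 0 by convention
  asn$signal_fc <- 10
  expect_equal(binding_strength_by_group(asn, cons)$H, 0)
  asn$signal_fc <- c(-1, 1, 1, 1, 1, 1)
  expect_error(binding_strength_by_group(asn, cons), "positive")
})

test_that("Kruskal-Wallis p is consistent with a permutation estimate", {
  set.seed(31)
  x <- c(rnorm(8), rnorm(8, 1.2))
  g <- rep(1:2, each = 8L)
  asn <- data.frame(gene_id = sprintf("g%d", 1:16), peak = "p",
                    summit_pos = 1L, distance_to_tss = 1L,
                    signal_fc = 10^x, closest = TRUE, stringsAsFactors = FALSE)
  cons <- list(levels = stats::setNames(g, asn$gene_id), S = 2L)
  out <- binding_strength_by_group(asn, cons)
  perm <- replicate(4000, {
    gg <- sample(g)
    stats::kruskal.test(x, factor(gg))$statistic
  })
  expect_lt(abs(out$p - mean(perm >= out$H - 1e-12)), 0.08)
})

test_that("the volcano join keeps one row per target with missing markers", {
  asn <- data.frame(gene_id = c("g1", "g2"), peak = c("p1", "p2"),
                    summit_pos = 1:2, distance_to_tss = 10L,
                    signal_fc = c(4, 8), closest = TRUE,
                    stringsAsFactors = FALSE)
  deg <- data.frame(gene_id = "g1", log2fc_expr = -2, category = "photo",
                    stringsAsFactors = FALSE)
  out <- volcano_join(deg, asn)
  expect_equal(nrow(out), 2L)
  expect_equal(out$log2fc_expr, c(-2, NA))
  expect_equal(out$log2_signal_fc, log2(c(4, 8)))
})

test_that("DEG fraction rises with conservation level on a planted cohort", {
  co <- default_cohort()
  focal <- co$config$species[[1]]
  pk <- read_narrowpeak(co$paths[[paste0("tf1_", focal)]])
  genes <- read_gene_table(co$paths[[paste0("genes_", focal)]])
  asn <- assign_peaks_to_genes(pk, genes,
                               co$config$promoter_window_bp[[focal]])
  orth <- read_orthogroups(co$paths$orthogroups, co$config$species)
  targets <- co$truth$targets_by_species
  cl <- conservation_levels(targets, orth, focal)
  expr <- utils::read.delim(co$paths$expression)
  rate <- deg_rate_by_conservation(cl, expr)
  # most vs least conserved group: clearly higher DEG fraction
  expect_gt(rate$fraction[5], rate$fraction[1])
  # binding strength increases with conservation (Kruskal rejects, medians order)
  bs <- binding_strength_by_group(asn, cl)
  expect_lt(bs$p, 1e-6)
  expect_gt(bs$summary$median_log10_signal[5], bs$summary$median_log10_signal[1])
})
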