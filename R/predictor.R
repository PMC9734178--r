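## Balanced-resampling random-forest prediction of DEG status from
## quantitative genome features and TF co-binding, with feature ablation and
## importance analysis.

#' Assemble the DEG-predictor feature table
#'
#' One row per target gene that is either a down-regulated DEG or a non-DEG
#' (up-regulated DEGs are excluded). Quantitative features are the binding
#' factors' signal fold-change at the closest summit, the summit-to-TSS
#' distance in bp and the wild-type expression level (FPKM). Each TF
#' co-binding (e.g. DAP-seq) peak set contributes a binary feature: 1 iff the
#' set overlaps the gene's 150 bp summit region. Genes missing a quantitative
#' feature are dropped (count reported via message).
#'
#' @param assignments assignment data.frame ([assign_peaks_to_genes()]);
#'   closest-summit rows are used. An optional `signal_fc2` column supplies a
#'   second factor's signal.
#' @param expression gene data.frame with `gene_id`, `fpkm_wt`, `is_deg`,
#'   `is_down`.
#' @param dap_peaks named list of co-binding peak data.frames (one per TF).
#' @param genes gene data.frame (for chromosome lookup).
#' @param summit_flank half-width of the summit region used for co-binding
#'   overlap (default 75, i.e. 150 bp regions).
#' @return data.frame: `gene_id`, `label` (factor non_DEG / DEG_down),
#'   feature columns; attribute `feature_groups` maps the ablation groups
#'   (signal, distance, expression, cobinding) to column names.
#' @export
assemble_features <- function(assignments, expression, dap_peaks, genes,
                              summit_flank = 75L) {
  cl <- assignments[assignments$closest, , drop = FALSE]
  m <- match(cl$gene_id, expression$gene_id)
  is_deg <- expression$is_deg[m]
  is_down <- expression$is_down[m]
  fpkm <- expression$fpkm_wt[m]
  keep_label <- !is.na(is_deg) & (!is_deg | (is_deg & is_down %in% TRUE))
  tab <- data.frame(gene_id = cl$gene_id,
                    label = factor(ifelse(is_deg, "DEG_down", "non_DEG"),
                                   levels = c("non_DEG", "DEG_down")),
                    signal_fc = cl$signal_fc,
                    distance_to_tss = cl$distance_to_tss,
                    fpkm_wt = fpkm, stringsAsFactors = FALSE)
  if (!is.null(cl$signal_fc2)) tab$signal_fc2 <- cl$signal_fc2
  chrom <- genes$chrom[match(cl$gene_id, genes$gene_id)]
  reg_start <- cl$summit_pos - summit_flank
  reg_end <- cl$summit_pos + summit_flank
  gr <- .as_granges(chrom, pmax(reg_start, 0L), reg_end)
  for (tf in names(dap_peaks)) {
    dp <- dap_peaks[[tf]]
    tab[[paste0("dap_", tf)]] <- as.integer(
      GenomicRanges::countOverlaps(gr, .as_granges(dp$chrom, dp$start, dp$end)) > 0L)
  }
  quant <- c("signal_fc", "distance_to_tss", "fpkm_wt",
             intersect("signal_fc2", names(tab)))
  complete <- stats::complete.cases(tab[, quant, drop = FALSE])
  keep <- keep_label & complete
  if (sum(!keep)) message(sum(!keep), " gene(s) dropped (up-regulated DEG or missing feature)")
  tab <- tab[keep, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "feature_groups") <- list(
    signal = intersect(c("signal_fc", "signal_fc2"), names(tab)),
    distance = "distance_to_tss",
    expression = "fpkm_wt",
    cobinding = grep("^dap_", names(tab), value = TRUE))
  tab
}

#' Drop co-binding features weakly correlated with the label
#'
#' Binary co-binding columns whose absolute point-biserial correlation
#' (Pearson on the 0/1 coding) with the label is below `r_min` are discarded;
#' constant columns correlate 0 and are dropped too.
#'
#' @param table feature table from [assemble_features()].
#' @param r_min correlation threshold (default 0.1).
#' @return the filtered table (retained co-binding columns reported via
#'   message); `feature_groups` attribute updated.
#' @export
filter_cobinding_features <- function(table, r_min = 0.1) {
  groups <- attr(table, "feature_groups")
  y <- as.integer(table$label) - 1L
  keep_col <- vapply(groups$cobinding, function(cc) {
    x <- table[[cc]]
    if (stats::sd(x) == 0) return(FALSE)
    abs(stats::cor(x, y)) >= r_min
  }, TRUE)
  dropped <- groups$cobinding[!keep_col]
  message("co-binding features retained: ",
          paste(groups$cobinding[keep_col], collapse = ", "),
          if (length(dropped)) paste0(" (dropped: ", paste(dropped, collapse = ", "), ")"))
  out <- table[, setdiff(names(table), dropped), drop = FALSE]
  groups$cobinding <- groups$cobinding[keep_col]
  attr(out, "feature_groups") <- groups
  out
}

# one balanced resampling repetition: downsample majority, 80/20 split,
# random forest, DEG-class metrics on the held-out 20%
.one_rf_rep <- function(tab, feat_cols, test_frac, num_trees, rep_seed) {
  set.seed(rep_seed)
  i_pos <- which(tab$label == "DEG_down")
  i_neg <- which(tab$label == "non_DEG")
  n_bal <- min(length(i_pos), length(i_neg))
  idx <- c(sample(i_pos, n_bal), sample(i_neg, n_bal))
  dat <- tab[idx, c("label", feat_cols), drop = FALSE]
  n <- nrow(dat)
  test <- sample.int(n, max(1L, round(test_frac * n)))
  train <- setdiff(seq_len(n), test)
  fit <- ranger::ranger(label ~ ., data = dat[train, , drop = FALSE],
                        num.trees = num_trees, probability = TRUE,
                        importance = "impurity", seed = rep_seed,
                        num.threads = 1L)
  pr <- stats::predict(fit, dat[test, , drop = FALSE],
                       num.threads = 1L)$predictions[, "DEG_down"]
  y <- dat$label[test] == "DEG_down"
  if (!any(y) || all(y)) return(NULL)   # degenerate split, caller retries
  yhat <- pr > 0.5
  tp <- sum(yhat & y); fp <- sum(yhat & !y); fn <- sum(!yhat & y)
  recall <- tp / (tp + fn)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(auc = auc_rank(pr, y), acc = mean(yhat == y), recall = recall, f1 = f1,
       importance = fit$variable.importance)
}

#' Balanced-resampling random-forest training
#'
#' Repeats `n_models` times: downsample the majority class to a balanced set,
#' split 80/20, fit a probability random forest, and score AUC / accuracy /
#' recall / F1 (DEG class) on the held-out 20%. The repetition seeds are
#' derived from `seed`, so the whole run is reproducible.
#'
#' @param table feature table ([assemble_features()], optionally filtered).
#' @param n_models number of resampled models (default 500).
#' @param test_frac held-out fraction (default 0.2).
#' @param seed master seed.
#' @param num_trees trees per forest (default 500).
#' @param feature_cols columns to use (default: all feature-group columns).
#' @return object of class `deg_rf_metrics`: `per_model` data.frame (auc,
#'   acc, recall, f1), `means`, `sds`, `importance` (n_models x p matrix),
#'   `feature_cols`, `n_models`, `seed`.
#' @export
resample_train <- function(table, n_models = 500L, test_frac = 0.2, seed = 1L,
                           num_trees = 500L, feature_cols = NULL) {
  groups <- attr(table, "feature_groups")
  if (is.null(feature_cols))
    feature_cols <- unlist(groups, use.names = FALSE)
  feature_cols <- intersect(feature_cols, names(table))
  if (!length(feature_cols)) stop("no feature columns left to train on")
  n_pos <- sum(table$label == "DEG_down")
  n_neg <- sum(table$label == "non_DEG")
  if (min(n_pos, n_neg) < 10L) stop("need >= 10 examples per class")
  reps <- vector("list", n_models)
  for (r in seq_len(n_models)) {
    rep_seed <- .derive_seed(seed, r)
    out <- NULL; tries <- 0L
    while (is.null(out) && tries < 5L) {
      out <- .one_rf_rep(table, feature_cols, test_frac, num_trees,
                         rep_seed + tries * 100003L)
      tries <- tries + 1L
    }
    if (is.null(out)) stop("class too small to produce a two-class test split")
    reps[[r]] <- out
  }
  per_model <- do.call(rbind, lapply(reps, function(r)
    data.frame(auc = r$auc, acc = r$acc, recall = r$recall, f1 = r$f1)))
  imp <- do.call(rbind, lapply(reps, `[[`, "importance"))
  structure(list(per_model = per_model,
                 means = colMeans(per_model), sds = apply(per_model, 2L, stats::sd),
                 importance = imp, feature_cols = feature_cols,
                 n_models = n_models, seed = seed),
            class = "deg_rf_metrics")
}

#' @export
print.deg_rf_metrics <- function(x, ...) {
  cat("Balanced-resampling random forest (", x$n_models, " models)\n", sep = "")
  m <- round(x$means, 3)
  cat("  mean AUC ", m[["auc"]], "  ACC ", m[["acc"]],
      "  Recall ", m[["recall"]], "  F1 ", m[["f1"]], "\n", sep = "")
  invisible(x)
}

#' Feature-group ablation
#'
#' Retrains the resampled forests with each feature group removed and
#' reports the AUC distribution and the mean drop relative to the full model.
#'
#' @param table feature table.
#' @param feature_groups named list of column-name vectors; must partition
#'   the table's feature columns (default: the table's `feature_groups`
#'   attribute).
#' @param n_models,seed,num_trees,test_frac as in [resample_train()].
#' @param full optional precomputed full-model `deg_rf_metrics` (recomputed
#'   when missing).
#' @return data.frame: `group`, `mean_auc`, `delta_auc` (full minus ablated),
#'   plus the `full` metrics in an attribute `full`.
#' @export
ablation <- function(table, feature_groups = attr(table, "feature_groups"),
                     n_models = 500L, seed = 1L, num_trees = 500L,
                     test_frac = 0.2, full = NULL) {
  all_cols <- unlist(feature_groups, use.names = FALSE)
  feat_in_table <- intersect(names(table),
                             unlist(attr(table, "feature_groups"), use.names = FALSE))
  if (!setequal(all_cols, feat_in_table) || anyDuplicated(all_cols))
    stop("feature_groups must partition the feature columns")
  if (is.null(full))
    full <- resample_train(table, n_models, test_frac, seed, num_trees,
                           feature_cols = all_cols)
  rows <- lapply(names(feature_groups), function(g) {
    keep <- setdiff(all_cols, feature_groups[[g]])
    if (!length(keep)) stop("removing group '", g, "' leaves no features")
    mm <- resample_train(table, n_models, test_frac, seed, num_trees,
                         feature_cols = keep)
    data.frame(group = g, mean_auc = mm$means[["auc"]],
               delta_auc = full$means[["auc"]] - mm$means[["auc"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}

#' Mean feature importance over the resampled models
#'
#' Impurity importances averaged over repetitions, ranked decreasing with
#' ties broken by feature name.
#'
#' @param metrics `deg_rf_metrics` from [resample_train()].
#' @return data.frame: `feature`, `mean_importance`, in rank order.
#' @export
mean_importance <- function(metrics) {
  mi <- colMeans(metrics$importance)
  ord <- order(-mi, names(mi))
  data.frame(feature = names(mi)[ord], mean_importance = unname(mi)[ord],
             stringsAsFactors = FALSE)
}
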