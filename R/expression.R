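## Joining DEG calls with target assignments: DEG overlap summaries, DEG rate
## by conservation group, binding strength by group (Kruskal-Wallis), and the
## volcano join table.

#' Summarize DEG overlap with a target set
#'
#' Counts DEGs, target DEGs and down-regulated target DEGs, and reports the
#' down-regulated percentage (to two decimals).
#'
#' @param targets character vector of target gene ids.
#' @param deg_table gene data.frame with `gene_id`, `is_deg`, `is_down`.
#' @return list: `n_deg`, `n_target_deg`, `n_down`, `pct_down` (`NA` when
#'   there are no target DEGs).
#' @export
summarize_deg_overlap <- function(targets, deg_table) {
  .stopifnot_cols(deg_table, c("gene_id", "is_deg", "is_down"), "deg_table")
  if (any(duplicated(deg_table$gene_id)))
    stop("duplicated gene_id rows in deg_table")
  if (any(deg_table$is_down & !deg_table$is_deg, na.rm = TRUE))
    stop("is_down set on non-DEG row(s)")
  is_t <- deg_table$gene_id %in% targets
  n_deg <- sum(deg_table$is_deg, na.rm = TRUE)
  n_td <- sum(deg_table$is_deg & is_t, na.rm = TRUE)
  n_down <- sum(deg_table$is_deg & deg_table$is_down & is_t, na.rm = TRUE)
  pct <- if (n_td > 0L) round(100 * n_down / n_td, 2L) else NA_real_
  list(n_deg = n_deg, n_target_deg = n_td, n_down = n_down, pct_down = pct)
}

#' DEG fraction per conservation group
#'
#' @param conservation result of [conservation_levels()].
#' @param deg_table gene data.frame with `gene_id`, `is_deg`.
#' @return data.frame: `level` (1..S), `n`, `n_deg`, `fraction` (`NA` for
#'   empty groups).
#' @export
deg_rate_by_conservation <- function(conservation, deg_table) {
  lev <- conservation$levels
  is_deg <- stats::setNames(deg_table$is_deg, deg_table$gene_id)[names(lev)]
  is_deg[is.na(is_deg)] <- FALSE
  out <- do.call(rbind, lapply(seq_len(conservation$S), function(l) {
    sel <- lev == l
    n <- sum(sel); nd <- sum(is_deg[sel])
    data.frame(level = l, n = n, n_deg = nd,
               fraction = if (n > 0L) nd / n else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Binding strength by conservation group
#'
#' Per gene, the statistic is log10 of the mean summit signal fold-change of
#' the binding factors at the gene's closest summit (the lone factor's value
#' in single-factor designs). Groups are compared by the Kruskal-Wallis rank
#' test (tie-corrected H, chi-square p on S-1 df); empty groups are dropped
#' with a warning.
#'
#' @param assignments assignment data.frame from [assign_peaks_to_genes()]
#'   (closest-summit rows are used); a `signal_fc2` column, when present, is
#'   averaged with `signal_fc` before the log.
#' @param conservation result of [conservation_levels()].
#' @return list: `summary` data.frame (`level`, `n`, `median_log10_signal`),
#'   `H`, `df`, `p`.
#' @export
binding_strength_by_group <- function(assignments, conservation) {
  cl <- assignments[assignments$closest, , drop = FALSE]
  sig <- cl$signal_fc
  if (!is.null(cl$signal_fc2)) sig <- (sig + cl$signal_fc2) / 2
  if (any(sig <= 0)) stop("signal fold-change must be positive for log10")
  lev <- conservation$levels[cl$gene_id]
  ok <- !is.na(lev)
  x <- log10(sig[ok]); g <- lev[ok]
  present <- sort(unique(g))
  if (length(present) < conservation$S)
    warning("empty conservation group(s) dropped: ",
            paste(setdiff(seq_len(conservation$S), present), collapse = ", "))
  if (length(present) < 2L) stop("need >= 2 non-empty groups")
  kt <- if (stats::var(x) == 0) {
    ## all observations tied: H = 0 by convention (kruskal.test returns NaN)
    list(statistic = c(H = 0), parameter = c(df = length(present) - 1L),
         p.value = 1)
  } else stats::kruskal.test(x, factor(g))
  summ <- do.call(rbind, lapply(present, function(l)
    data.frame(level = l, n = sum(g == l),
               median_log10_signal = stats::median(x[g == l]))))
  list(summary = summ, H = unname(kt$statistic),
       df = unname(kt$parameter), p = kt$p.value)
}

#' Join expression change with binding for every target gene
#'
#' One row per target gene: expression log2 fold-change (WT vs mutant), log2
#' binding signal at the closest summit, conservation level and category.
#' Targets without expression data keep their row with `NA` in the expression
#' columns.
#'
#' @param deg_table gene data.frame with `gene_id`, `log2fc_expr` (and
#'   optionally `is_deg`, `category`).
#' @param assignments assignment data.frame (closest rows used).
#' @param conservation optional [conservation_levels()] result.
#' @return data.frame: `gene_id`, `log2fc_expr`, `log2_signal_fc`,
#'   `conservation_level`, `category`.
#' @export
volcano_join <- function(deg_table, assignments, conservation = NULL) {
  cl <- assignments[assignments$closest, , drop = FALSE]
  m <- match(cl$gene_id, deg_table$gene_id)
  out <- data.frame(gene_id = cl$gene_id,
                    log2fc_expr = if ("log2fc_expr" %in% names(deg_table))
                      deg_table$log2fc_expr[m] else NA_real_,
                    log2_signal_fc = log2(cl$signal_fc),
                    conservation_level = if (!is.null(conservation))
                      unname(conservation$levels[cl$gene_id]) else NA_integer_,
                    category = if ("category" %in% names(deg_table))
                      deg_table$category[m] else NA_character_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
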