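## Synthetic multi-species cohort generator with planted ground truth.
##
## The generator emulates the statistical structure of a cross-species TF
## ChIP-seq study: a 5-species cohort where a fraction of orthogroups are TF
## targets, target conservation levels follow the empirical distribution of
## the focal species' target partition, conserved sites carry stronger
## binding signal, bound motif instances show reduced nucleotide diversity,
## DEG status is driven by binding strength, TSS distance, expression level
## and TF co-binding through a logistic model, and duplicate pairs retain or
## lose binding with correspondingly graded expression correlation.

#' Configuration of a synthetic cohort
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' five species with promoter windows 1500/2500/2000/1500/2500 bp, 2000
#' orthogroups of which 48% are targets of the focal species, conservation
#' levels drawn with weights (375, 205, 151, 100, 129)/960 for levels 1..5,
#' a 2x signal boost graded across conservation levels, a 0.2 diversity
#' shrinkage at bound motifs, and a DEG logistic model in which co-binding
#' carries the largest coefficient.
#'
#' @param n_species number of species (>= 2).
#' @param species species names (focal species first).
#' @param n_orthogroups number of orthogroups (one focal gene each).
#' @param frac_target fraction of orthogroups that are focal targets.
#' @param frac_conserved fraction of target orthogroups bound in all species.
#' @param level_weights relative weights of conservation levels 1..S-1 for
#'   non-fully-conserved targets.
#' @param frac_photo fraction of fully conserved target orthogroups labeled
#'   "photosynthesis".
#' @param conserved_signal_boost signal multiplier at level S (graded as
#'   `boost^((level-1)/(S-1))` in between).
#' @param pi_constraint_factor multiplier (< 1) on alt-allele frequency at
#'   constrained (bound) motif positions.
#' @param deg_coefficients named coefficients of the DEG logistic model:
#'   `intercept`, `signal`, `distance`, `expression`, `cobinding` (applied to
#'   standardized features).
#' @param promoter_window_bp named per-species promoter windows (bp).
#' @param motif_consensus IUPAC consensus planted at bound summits.
#' @param motif_bg_frac fraction of unbound open-chromatin summits that also
#'   carry a planted motif (the unbound background class).
#' @param site_density per-bp probability that a position inside an
#'   open-chromatin region segregates in the variant panel.
#' @param n_haplotypes haplotypes in the variant panel.
#' @param n_dap_tfs number of co-binding TF peak sets; the first
#'   `n_informative_dap` drive DEG status.
#' @param n_informative_dap informative co-binding TFs.
#' @param n_duplicate_pairs duplicate pairs (split evenly over retention
#'   classes both/single/none).
#' @param n_tissues tissues in the duplicate-pair expression matrix.
#' @param n_unplaced extra focal genes placed in no orthogroup.
#' @param deg_rate_nontarget DEG rate among non-target genes.
#' @param frac_down fraction of DEGs that are down-regulated.
#' @param fasta_species `"focal"` (default) or `"all"`: which genomes to emit.
#' @param seed master RNG seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_species = 5L,
                          species = c("arabidopsis", "tobacco", "tomato",
                                      "rice", "maize")[seq_len(n_species)],
                          n_orthogroups = 2000L,
                          frac_target = 0.48,
                          frac_conserved = 129 / 960,
                          level_weights = c(375, 205, 151, 100),
                          frac_photo = 0.6,
                          conserved_signal_boost = 2,
                          pi_constraint_factor = 0.2,
                          deg_coefficients = c(intercept = -1.3, signal = 0.8,
                                               distance = 0.8, expression = 0.8,
                                               cobinding = 1.6),
                          promoter_window_bp = stats::setNames(
                            c(1500L, 2500L, 2000L, 1500L, 2500L)[seq_len(n_species)],
                            species),
                          motif_consensus = "RGATTYY",
                          motif_bg_frac = 0.7,
                          site_density = 0.3,
                          n_haplotypes = 1000L,
                          n_dap_tfs = 6L,
                          n_informative_dap = 2L,
                          n_duplicate_pairs = 150L,
                          n_tissues = 12L,
                          n_unplaced = 10L,
                          deg_rate_nontarget = 0.1,
                          frac_down = 0.7594,
                          fasta_species = c("focal", "all"),
                          seed = 1L) {
  fasta_species <- match.arg(fasta_species)
  cfg <- list(n_species = as.integer(n_species), species = species,
              n_orthogroups = as.integer(n_orthogroups),
              frac_target = frac_target, frac_conserved = frac_conserved,
              level_weights = level_weights, frac_photo = frac_photo,
              conserved_signal_boost = conserved_signal_boost,
              pi_constraint_factor = pi_constraint_factor,
              deg_coefficients = deg_coefficients,
              promoter_window_bp = promoter_window_bp,
              motif_consensus = motif_consensus,
              motif_bg_frac = motif_bg_frac, site_density = site_density,
              n_haplotypes = as.integer(n_haplotypes),
              n_dap_tfs = as.integer(n_dap_tfs),
              n_informative_dap = as.integer(n_informative_dap),
              n_duplicate_pairs = as.integer(n_duplicate_pairs),
              n_tissues = as.integer(n_tissues),
              n_unplaced = as.integer(n_unplaced),
              deg_rate_nontarget = deg_rate_nontarget,
              frac_down = frac_down, fasta_species = fasta_species,
              seed = as.integer(seed))
  fr <- c(cfg$frac_target, cfg$frac_conserved, cfg$frac_photo,
          cfg$motif_bg_frac, cfg$site_density, cfg$deg_rate_nontarget,
          cfg$frac_down)
  if (any(fr < 0 | fr > 1)) stop("config fractions must lie in [0, 1]")
  if (cfg$pi_constraint_factor <= 0 || cfg$pi_constraint_factor > 1)
    stop("pi_constraint_factor must lie in (0, 1]")
  if (cfg$n_species < 2L) stop("need at least 2 species")
  if (length(cfg$species) != cfg$n_species) stop("species names do not match n_species")
  if (!all(cfg$species %in% names(cfg$promoter_window_bp)))
    stop("promoter_window_bp must be named for every species")
  if (length(cfg$level_weights) != cfg$n_species - 1L)
    stop("level_weights must have length n_species - 1")
  class(cfg) <- "cohort_config"
  cfg
}

# a concrete random realization of an IUPAC consensus
.realize_iupac <- function(consensus, n) {
  sym <- .check_iupac(consensus)
  choices <- lapply(sym, function(s) strsplit(.IUPAC[[s]], "")[[1]])
  vapply(seq_len(n), function(i)
    paste(vapply(choices, function(ch) ch[sample.int(length(ch), 1L)], ""),
          collapse = ""), "")
}

.z <- function(x) if (stats::sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / stats::sd(x)

#' Generate a synthetic multi-species cohort on disk
#'
#' Writes per-species gene tables, TF (two paralogous factors) and
#' open-chromatin narrowPeak sets, a genome FASTA with planted consensus
#' instances, an Orthogroups.tsv, a variant panel, an expression table with
#' DEG labels, co-binding peak sets, duplicate pairs with a tissue expression
#' matrix, and a `ground_truth.json` describing everything planted.
#' Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with `paths` (named file paths), `truth` (the
#'   ground-truth list) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), dir) {
  stopifnot(inherits(config, "cohort_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  S <- config$n_species
  species <- config$species
  focal <- species[[1]]
  n_og <- config$n_orthogroups
  wmax <- max(config$promoter_window_bp)
  spacing <- 2L * wmax + 1000L
  motif_len <- nchar(config$motif_consensus)

  ## --- orthogroups, targets, conservation levels -------------------------
  og_ids <- sprintf("OG%06d", seq_len(n_og))
  n_target <- round(config$frac_target * n_og)
  target_og <- sort(sample.int(n_og, n_target))
  lev <- integer(n_og)
  is_cons <- stats::runif(n_target) < config$frac_conserved
  lev[target_og[is_cons]] <- S
  n_rest <- sum(!is_cons)
  lev[target_og[!is_cons]] <- sample(seq_len(S - 1L), n_rest, replace = TRUE,
                                     prob = config$level_weights)
  ## bound species per target orthogroup: focal + (level-1) others
  bound <- matrix(FALSE, n_og, S, dimnames = list(og_ids, species))
  for (og in target_og) {
    others <- if (lev[og] > 1L) sample(species[-1], lev[og] - 1L) else character()
    bound[og, c(focal, others)] <- TRUE
  }
  ## categories at orthogroup level
  category <- rep("other", n_og)
  pool <- c("metabolism", "stress", "development")
  category[seq_len(n_og)] <- sample(pool, n_og, replace = TRUE)
  cons_target <- target_og[lev[target_og] == S]
  photo <- cons_target[stats::runif(length(cons_target)) < config$frac_photo]
  category[photo] <- "photosynthesis"

  ## --- per-species genes and peaks ---------------------------------------
  paths <- list()
  gene_tabs <- list()
  tf1_tabs <- list(); tf2_tabs <- list(); atac_tabs <- list()
  truth_targets <- list()
  for (si in seq_along(species)) {
    s <- species[[si]]
    win <- config$promoter_window_bp[[s]]
    n_extra <- config$n_unplaced
    n_genes <- n_og + n_extra
    gid <- c(sprintf("%s_g%05d", s, seq_len(n_og)),
             sprintf("%s_u%03d", s, seq_len(n_extra)))
    tss <- 3000L + (seq_len(n_genes) - 1L) * spacing
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- data.frame(gene_id = gid, chrom = "chr1", tss = tss,
                        strand = strand, species = s,
                        category = c(category, rep("other", n_extra)),
                        stringsAsFactors = FALSE)
    is_bound <- c(bound[, s], rep(FALSE, n_extra))
    if (si == 1L && n_extra >= 2L)       # a few unplaced focal targets (level 1)
      is_bound[n_og + seq_len(max(2L, n_extra %/% 2L))] <- TRUE
    bi <- which(is_bound)
    dist <- 50L + floor(stats::runif(length(bi)) * (win - 150L))
    summit <- ifelse(strand[bi] == "+", tss[bi] - dist, tss[bi] + dist)
    glev <- ifelse(bi <= n_og, lev[pmin(bi, n_og)], 1L)
    boost <- config$conserved_signal_boost ^ ((glev - 1) / max(1L, S - 1L))
    sig1 <- stats::rlnorm(length(bi), meanlog = 1, sdlog = 0.5) * boost
    sig2 <- sig1 * exp(stats::rnorm(length(bi), 0, 0.15))
    tf <- data.frame(chrom = "chr1", start = summit - 100L, end = summit + 100L,
                     name = sprintf("%s_tfpk_%05d", s, seq_along(bi)),
                     score = 0, strand = ".", signal_fc = sig1,
                     pvalue_neglog10 = -1, qvalue_neglog10 = -1,
                     summit_offset = 100L,
                     idr = round(stats::runif(length(bi), 0, 0.009), 6),
                     stringsAsFactors = FALSE)
    tf2 <- tf
    tf2$signal_fc <- sig2
    tf2 <- tf2[sort(sample.int(nrow(tf2), round(0.95 * nrow(tf2)))), , drop = FALSE]
    ## open chromatin at every gene; bound genes share the TF summit
    oc_dist <- 50L + floor(stats::runif(n_genes) * (win - 150L))
    oc_summit <- ifelse(strand == "+", tss - oc_dist, tss + oc_dist)
    oc_summit[bi] <- summit
    atac <- data.frame(chrom = "chr1", start = oc_summit - 150L,
                       end = oc_summit + 150L,
                       name = sprintf("%s_ocpk_%05d", s, seq_len(n_genes)),
                       score = 0, strand = ".",
                       signal_fc = stats::rlnorm(n_genes, 0.5, 0.4),
                       pvalue_neglog10 = -1, qvalue_neglog10 = -1,
                       summit_offset = 150L, stringsAsFactors = FALSE)
    gene_tabs[[s]] <- genes
    tf1_tabs[[s]] <- tf; tf2_tabs[[s]] <- tf2; atac_tabs[[s]] <- atac
    truth_targets[[s]] <- gid[is_bound]
    paths[[paste0("genes_", s)]] <- file.path(dir, paste0("genes_", s, ".tsv"))
    write_gene_table(genes, paths[[paste0("genes_", s)]])
    paths[[paste0("tf1_", s)]] <- file.path(dir, paste0("tf1_", s, ".narrowPeak"))
    write_narrowpeak(tf, paths[[paste0("tf1_", s)]])
    paths[[paste0("tf2_", s)]] <- file.path(dir, paste0("tf2_", s, ".narrowPeak"))
    write_narrowpeak(tf2, paths[[paste0("tf2_", s)]])
    paths[[paste0("atac_", s)]] <- file.path(dir, paste0("atac_", s, ".narrowPeak"))
    write_narrowpeak(atac, paths[[paste0("atac_", s)]])
  }

  ## --- Orthogroups.tsv ----------------------------------------------------
  og_lines <- c(paste(c("Orthogroup", species), collapse = "\t"),
                vapply(seq_len(n_og), function(i)
                  paste(c(og_ids[i],
                          vapply(species, function(s)
                            sprintf("%s_g%05d", s, i), "")), collapse = "\t"), ""))
  paths$orthogroups <- file.path(dir, "Orthogroups.tsv")
  writeLines(og_lines, paths$orthogroups)

  ## --- focal genome FASTA with planted motifs -----------------------------
  fasta_for <- if (config$fasta_species == "all") species else focal
  planted <- list()
  for (s in fasta_for) {
    genes <- gene_tabs[[s]]
    chrom_len <- max(genes$tss) + spacing
    bases <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    tf <- tf1_tabs[[s]]
    atac <- atac_tabs[[s]]
    bound_summit <- tf$start + tf$summit_offset
    half <- motif_len %/% 2L
    plant_at <- function(pos0) {
      word <- .realize_iupac(config$motif_consensus, 1L)
      bases[(pos0 + 1L):(pos0 + motif_len)] <<- strsplit(word, "")[[1]]
      pos0
    }
    bound_pos <- as.integer(vapply(bound_summit - half, plant_at, numeric(1)))
    ## bound regions carry extra motif copies (higher motif density at true
    ## binding sites), placed in non-overlapping slots within the summit region
    slots <- c(-60L, -45L, -30L, -15L, 15L, 30L, 45L)
    extra_pos <- unlist(lapply(bound_summit, function(sm) {
      k <- min(stats::rpois(1L, 1), length(slots))
      if (k == 0L) return(integer())
      vapply(sm + sample(slots, k) - half, plant_at, numeric(1))
    }))
    bound_pos <- sort(c(bound_pos, as.integer(extra_pos)))
    oc_summit <- atac$start + atac$summit_offset
    is_bound_region <- GenomicRanges::countOverlaps(
      .as_granges("chr1", oc_summit - half, oc_summit - half + motif_len),
      .as_granges("chr1", tf$start, tf$end)) > 0L
    cand <- which(!is_bound_region)
    bg_sel <- cand[stats::runif(length(cand)) < config$motif_bg_frac]
    bg_pos <- as.integer(vapply(oc_summit[bg_sel] - half, plant_at, numeric(1)))
    dna <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
    names(dna) <- "chr1"
    paths[[paste0("genome_", s)]] <- file.path(dir, paste0("genome_", s, ".fa"))
    Biostrings::writeXStringSet(dna, paths[[paste0("genome_", s)]], width = 80L)
    planted[[s]] <- list(bound_motif_start = bound_pos,
                         background_motif_start = bg_pos)
  }

  ## --- variant panel over focal open chromatin ----------------------------
  atac <- atac_tabs[[focal]]
  oc_pos <- unlist(lapply(seq_len(nrow(atac)), function(i)
    atac$start[i]:(atac$end[i] - 1L)))
  oc_pos <- unique(oc_pos)
  seg <- oc_pos[stats::runif(length(oc_pos)) < config$site_density]
  a <- stats::rbeta(length(seg), 0.3, 3)
  a <- pmin(a, 0.5)
  constrained_pos <- unlist(lapply(planted[[focal]]$bound_motif_start,
                                   function(p) p:(p + motif_len - 1L)))
  is_con <- seg %in% constrained_pos
  a[is_con] <- a[is_con] * config$pi_constraint_factor
  a <- round(a, 6)   # 6-decimal alleles so the written pair sums exactly to 1
  panel <- data.frame(chrom = "chr1", pos = seg,
                      n_haplotypes = config$n_haplotypes,
                      freqs = paste0(sprintf("%.6f", 1 - a), ",",
                                     sprintf("%.6f", a)),
                      stringsAsFactors = FALSE)
  panel <- panel[order(panel$pos), , drop = FALSE]
  paths$variants <- file.path(dir, paste0("variants_", focal, ".tsv"))
  utils::write.table(panel, paths$variants, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- co-binding (DAP-seq style) peak sets -------------------------------
  genes_f <- gene_tabs[[focal]]
  tf_f <- tf1_tabs[[focal]]
  target_idx <- match(truth_targets[[focal]],
                      genes_f$gene_id)               # bound focal genes
  summit_f <- tf_f$start + tf_f$summit_offset        # aligned with target_idx
  dap_names <- sprintf("TF%02d", seq_len(config$n_dap_tfs))
  dap_bits <- matrix(0L, length(target_idx), config$n_dap_tfs,
                     dimnames = list(genes_f$gene_id[target_idx], dap_names))
  for (j in seq_len(config$n_dap_tfs)) {
    p_bind <- if (j <= config$n_informative_dap) 0.5 else 0.3
    dap_bits[, j] <- as.integer(stats::runif(length(target_idx)) < p_bind)
    on_idx <- which(dap_bits[, j] == 1L)
    extra <- sample(setdiff(seq_len(n_og), target_idx),
                    min(200L, n_og - length(target_idx)))
    oc_f <- atac_tabs[[focal]]
    extra_summit <- oc_f$start[extra] + oc_f$summit_offset[extra]
    ctr <- c(summit_f[on_idx], extra_summit)
    dap <- data.frame(chrom = "chr1", start = ctr - 50L, end = ctr + 50L,
                      name = sprintf("%s_dap_%05d", dap_names[j], seq_along(ctr)),
                      score = 0, strand = ".",
                      signal_fc = stats::rlnorm(length(ctr), 0.5, 0.3),
                      pvalue_neglog10 = -1, qvalue_neglog10 = -1,
                      summit_offset = 50L, stringsAsFactors = FALSE)
    paths[[paste0("dap_", dap_names[j])]] <-
      file.path(dir, paste0("dap_", dap_names[j], ".narrowPeak"))
    write_narrowpeak(dap, paths[[paste0("dap_", dap_names[j])]])
  }

  ## --- expression + DEG labels (focal) ------------------------------------
  n_genes_f <- nrow(genes_f)
  fpkm <- stats::rlnorm(n_genes_f, meanlog = 3, sdlog = 1)
  dist_f <- abs(genes_f$tss[target_idx] - summit_f)
  sig_mean <- (tf_f$signal_fc +
                 tf2_tabs[[focal]]$signal_fc[match(tf_f$name, tf2_tabs[[focal]]$name)])
  sig_mean <- ifelse(is.na(sig_mean), tf_f$signal_fc, sig_mean / 2)
  b <- config$deg_coefficients
  k_inf <- rowSums(dap_bits[, seq_len(config$n_informative_dap), drop = FALSE])
  linp <- b[["intercept"]] +
    b[["signal"]] * .z(log10(sig_mean)) +
    b[["distance"]] * .z(-dist_f) +
    b[["expression"]] * .z(log10(fpkm[target_idx] + 1)) +
    b[["cobinding"]] * .z(k_inf)
  p_deg <- stats::plogis(linp)
  is_deg <- logical(n_genes_f)
  is_deg[target_idx] <- stats::runif(length(target_idx)) < p_deg
  nt <- setdiff(seq_len(n_genes_f), target_idx)
  is_deg[nt] <- stats::runif(length(nt)) < config$deg_rate_nontarget
  is_down <- rep(FALSE, n_genes_f)
  is_down[is_deg] <- stats::runif(sum(is_deg)) < config$frac_down
  l2fc <- stats::rnorm(n_genes_f, 0, 0.25)
  l2fc[is_deg & is_down] <- -abs(stats::rnorm(sum(is_deg & is_down), 2, 0.7))
  l2fc[is_deg & !is_down] <- abs(stats::rnorm(sum(is_deg & !is_down), 2, 0.7))
  expr <- data.frame(gene_id = genes_f$gene_id, fpkm_wt = round(fpkm, 4),
                     is_deg = is_deg, is_down = is_down,
                     log2fc_expr = round(l2fc, 4), stringsAsFactors = FALSE)
  paths$expression <- file.path(dir, paste0("expression_", focal, ".tsv"))
  utils::write.table(expr, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- duplicate pairs + tissue expression (focal) ------------------------
  npc <- config$n_duplicate_pairs %/% 3L
  tgt_genes <- genes_f$gene_id[target_idx]
  non_genes <- genes_f$gene_id[nt]
  if (length(tgt_genes) < 3L * npc || length(non_genes) < 3L * npc)
    stop("n_duplicate_pairs = ", config$n_duplicate_pairs,
         " needs at least ", 3L * npc, " target and non-target genes each; ",
         "the cohort has ", length(tgt_genes), " and ", length(non_genes),
         " (reduce n_duplicate_pairs or raise n_orthogroups)")
  pick <- function(pool, n) sample(pool, n)
  g_both <- matrix(pick(tgt_genes, 2L * npc), ncol = 2L)
  g_single <- cbind(pick(setdiff(tgt_genes, c(g_both)), npc),
                    pick(non_genes, npc))
  g_none <- matrix(pick(setdiff(non_genes, c(g_single)), 2L * npc), ncol = 2L)
  pairs <- data.frame(gene_a = c(g_both[, 1], g_single[, 1], g_none[, 1]),
                      gene_b = c(g_both[, 2], g_single[, 2], g_none[, 2]),
                      origin = "synteny", stringsAsFactors = FALSE)
  true_ret <- rep(c("both", "single", "none"), each = npc)
  rho <- c(both = 0.8, single = 0.4, none = 0)[true_ret]
  tis <- matrix(NA_real_, 2L * nrow(pairs), config$n_tissues)
  rn <- character(2L * nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    za <- stats::rnorm(config$n_tissues)
    zb <- rho[i] * za + sqrt(1 - rho[i]^2) * stats::rnorm(config$n_tissues)
    tis[2L * i - 1L, ] <- round(exp(1 + 0.8 * za), 4)
    tis[2L * i, ] <- round(exp(1 + 0.8 * zb), 4)
    rn[2L * i - 1L] <- pairs$gene_a[i]; rn[2L * i] <- pairs$gene_b[i]
  }
  rownames(tis) <- rn
  colnames(tis) <- sprintf("tissue%02d", seq_len(config$n_tissues))
  paths$duplicate_pairs <- file.path(dir, paste0("duplicate_pairs_", focal, ".tsv"))
  utils::write.table(pairs, paths$duplicate_pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$tissue_expression <- file.path(dir, paste0("expression_tissues_", focal, ".tsv"))
  utils::write.table(data.frame(gene_id = rownames(tis), tis,
                                check.names = FALSE, stringsAsFactors = FALSE),
                     paths$tissue_expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- ground truth --------------------------------------------------------
  truth <- list(
    species = species, focal = focal,
    target_og = og_ids[target_og],
    conservation_level = stats::setNames(lev[target_og], og_ids[target_og]),
    focal_target_levels = stats::setNames(
      ifelse(match(truth_targets[[focal]], genes_f$gene_id) <= n_og,
             lev[pmin(match(truth_targets[[focal]], genes_f$gene_id), n_og)], 1L),
      truth_targets[[focal]]),
    targets_by_species = truth_targets,
    category_by_og = stats::setNames(category, og_ids),
    planted_motifs = planted,
    p_deg = stats::setNames(round(p_deg, 6), genes_f$gene_id[target_idx]),
    dap_informative = dap_names[seq_len(config$n_informative_dap)],
    dap_bits = data.frame(gene_id = rownames(dap_bits), dap_bits,
                          row.names = NULL, stringsAsFactors = FALSE),
    pair_retention = true_ret,
    config = unclass(config))
  paths$ground_truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, truth = truth, config = config))
}

#' Tiny hand-checkable worked-example cohort
#'
#' Writes a fixed three-species cohort (no randomness: every value is a
#' literal) whose expected results at every stage can be verified by hand,
#' and returns them alongside the file paths. Orthogroup og1 is bound in all
#' three species (conservation level 3), og2 in two (level 2), og3 only in
#' the focal species (level 1), og4 is unbound; one extra focal gene sits in
#' no orthogroup and is bound (level 1 by convention). The focal genome
#' carries one planted motif whose first position segregates at p = (0.5,
#' 0.5) over 10 haplotypes (per-site diversity 10/9 * 0.5) while all other
#' positions are invariant, and one duplicate pair has identical signals.
#'
#' @param dir output directory.
#' @return list with `paths`, `config` fields (`species`, `focal`,
#'   `windows`), and `expected` (levels, group sizes, motif diversity,
#'   retention labels).
#' @export
worked_example_cohort <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  species <- c("speciesA", "speciesB", "speciesC")
  paths <- list()
  ## genes: 5 focal (4 orthogroup members + 1 unplaced), 4 in B and C
  mk_genes <- function(s, n) {
    data.frame(gene_id = sprintf("%s_g%d", s, seq_len(n)), chrom = "chr1",
               tss = 3000L + (seq_len(n) - 1L) * 4000L, strand = "+",
               species = s,
               category = c("photosynthesis", "photosynthesis", "other",
                            "other", "other")[seq_len(n)],
               stringsAsFactors = FALSE)
  }
  gA <- mk_genes("speciesA", 5L); gA$gene_id[5] <- "speciesA_u1"
  gB <- mk_genes("speciesB", 4L); gC <- mk_genes("speciesC", 4L)
  paths$genes_speciesA <- file.path(dir, "genes_speciesA.tsv")
  paths$genes_speciesB <- file.path(dir, "genes_speciesB.tsv")
  paths$genes_speciesC <- file.path(dir, "genes_speciesC.tsv")
  write_gene_table(gA, paths$genes_speciesA)
  write_gene_table(gB, paths$genes_speciesB)
  write_gene_table(gC, paths$genes_speciesC)
  ## orthogroups og1..og4: gene i of each species; focal u1 unplaced
  writeLines(c(paste(c("Orthogroup", species), collapse = "\t"),
               vapply(1:4, function(i)
                 paste(c(sprintf("og%d", i),
                         sprintf("%s_g%d", species, i)), collapse = "\t"), "")),
             fp <- file.path(dir, "Orthogroups.tsv"))
  paths$orthogroups <- fp
  ## bound genes: A: g1 g2 g3 u1; B: g1 g2; C: g1
  mk_peaks <- function(s, genes, idx, sig) {
    summit <- genes$tss[idx] - 500L
    data.frame(chrom = "chr1", start = summit - 100L, end = summit + 100L,
               name = sprintf("%s_tfpk_%d", s, seq_along(idx)), score = 0,
               strand = ".", signal_fc = sig, pvalue_neglog10 = -1,
               qvalue_neglog10 = -1, summit_offset = 100L, idr = 0.005,
               stringsAsFactors = FALSE)
  }
  pA <- mk_peaks("speciesA", gA, c(1L, 2L, 3L, 5L), c(8, 6, 3, 2))
  pB <- mk_peaks("speciesB", gB, c(1L, 2L), c(7, 5))
  pC <- mk_peaks("speciesC", gC, 1L, 9)
  paths$tf1_speciesA <- file.path(dir, "tf1_speciesA.narrowPeak")
  paths$tf1_speciesB <- file.path(dir, "tf1_speciesB.narrowPeak")
  paths$tf1_speciesC <- file.path(dir, "tf1_speciesC.narrowPeak")
  write_narrowpeak(pA, paths$tf1_speciesA)
  write_narrowpeak(pB, paths$tf1_speciesB)
  write_narrowpeak(pC, paths$tf1_speciesC)
  ## open chromatin at every focal gene promoter (same summits for bound)
  ocs <- c(gA$tss[1:4] - 500L, gA$tss[5] - 500L)
  atac <- data.frame(chrom = "chr1", start = ocs - 150L, end = ocs + 150L,
                     name = sprintf("speciesA_ocpk_%d", 1:5), score = 0,
                     strand = ".", signal_fc = 1, pvalue_neglog10 = -1,
                     qvalue_neglog10 = -1, summit_offset = 150L,
                     stringsAsFactors = FALSE)
  paths$atac_speciesA <- file.path(dir, "atac_speciesA.narrowPeak")
  write_narrowpeak(atac, paths$atac_speciesA)
  ## focal genome: A-runs with one planted AGATTCC at the g1 summit and one
  ## at the unbound g4 open-chromatin summit
  len <- max(gA$tss) + 4000L
  bases <- rep("A", len)
  plant <- function(pos0) bases[(pos0 + 1L):(pos0 + 7L)] <<- strsplit("AGATTCC", "")[[1]]
  bound_motif <- gA$tss[1] - 500L - 3L
  bg_motif <- gA$tss[4] - 500L - 3L
  plant(bound_motif); plant(bg_motif)
  dna <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(dna) <- "chr1"
  paths$genome_speciesA <- file.path(dir, "genome_speciesA.fa")
  Biostrings::writeXStringSet(dna, paths$genome_speciesA, width = 80L)
  ## variant panel: first motif position of the bound motif at p=(0.5,0.5),
  ## n=10; everything else invariant (absent)
  writeLines(c("chrom\tpos\tn_haplotypes\tfreqs",
               sprintf("chr1\t%d\t10\t0.5,0.5", bound_motif)),
             fp <- file.path(dir, "variants_speciesA.tsv"))
  paths$variants <- fp
  ## expression: g1 and g2 DEG (down), others not
  expr <- data.frame(gene_id = gA$gene_id, fpkm_wt = c(50, 20, 10, 5, 2),
                     is_deg = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                     is_down = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                     log2fc_expr = c(-2.5, -1.8, 0.1, -0.05, 0.2),
                     stringsAsFactors = FALSE)
  paths$expression <- file.path(dir, "expression_speciesA.tsv")
  utils::write.table(expr, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ## duplicate pairs: (g1, g2) both bound with identical signals; (g3, g4)
  ## single; (g4, u1 unbound? u1 is bound) -> use (g4, g4)? keep two pairs
  pairs <- data.frame(gene_a = c("speciesA_g1", "speciesA_g3"),
                      gene_b = c("speciesA_g2", "speciesA_g4"),
                      origin = "synteny", stringsAsFactors = FALSE)
  paths$duplicate_pairs <- file.path(dir, "duplicate_pairs_speciesA.tsv")
  utils::write.table(pairs, paths$duplicate_pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expected <- list(
    levels = c(speciesA_g1 = 3L, speciesA_g2 = 2L, speciesA_g3 = 1L,
               speciesA_u1 = 1L),
    groups = c(`1` = 2L, `2` = 1L, `3` = 1L),
    bound_motif_start = bound_motif, background_motif_start = bg_motif,
    bound_motif_pi = (10 / 9) * 0.5 / 7,   # one segregating position of 7
    background_motif_pi = 0,
    retention = c("both", "single"),
    pct_down = 100)
  list(paths = paths,
       config = list(species = species, focal = "speciesA",
                     windows = stats::setNames(rep(1500L, 3), species)),
       expected = expected)
}
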