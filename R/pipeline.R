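## End-to-end orchestration: a single config drives target assignment,
## conservation, motif diversity, expression integration, the DEG predictor,
## the k-mer model and the duplication analysis, writing a report directory
## whose contents are a pure function of (inputs, config, seed).

#' Build a pipeline config for a generated cohort
#'
#' Convenience constructor mapping the files written by [generate_cohort()]
#' (or [worked_example_cohort()]) onto the pipeline-config schema consumed by
#' [run_all()].
#'
#' @param cohort result of [generate_cohort()].
#' @param stages stages to run (default: all available given the inputs).
#' @param n_models,num_trees resampling and forest sizes for the predictor.
#' @param seed pipeline seed.
#' @return a named list (the config); serialisable to YAML.
#' @export
pipeline_config <- function(cohort,
                            stages = c("targets", "conservation", "kmer",
                                       "diversity", "integration",
                                       "predictor", "duplication"),
                            n_models = 500L, num_trees = 500L, seed = 1L) {
  cfg <- cohort$config
  species <- cfg$species
  p <- cohort$paths
  pick <- function(prefix) {
    out <- lapply(species, function(s) p[[paste0(prefix, s)]])
    names(out) <- species
    out[!vapply(out, is.null, TRUE)]
  }
  dap <- p[grep("^dap_", names(p))]
  names(dap) <- sub("^dap_", "", names(dap))
  list(species = as.list(species), focal = species[[1]],
       windows = as.list(cfg$promoter_window_bp),
       idr_max = 0.01, signal_min = 0, summit_flank = 75L,
       motif = if (!is.null(cfg$motif_consensus)) cfg$motif_consensus else "RGATTYY",
       stages = as.list(stages),
       predictor = list(n_models = n_models, num_trees = num_trees, r_min = 0.1),
       kmer = list(k = 7L, width = 150L, test_frac = 0.2),
       seed = as.integer(seed),
       inputs = list(genes = pick("genes_"), tf1 = pick("tf1_"),
                     tf2 = pick("tf2_"), atac = pick("atac_"),
                     orthogroups = p$orthogroups,
                     genome = p[[paste0("genome_", species[[1]])]],
                     variants = p$variants, expression = p$expression,
                     dap = dap, duplicate_pairs = p$duplicate_pairs,
                     tissue_expression = p$tissue_expression))
}

.stage_requirements <- list(
  targets = c("genes", "tf1"),
  conservation = c("genes", "tf1", "orthogroups"),
  kmer = c("tf1", "atac", "genome"),
  diversity = c("tf1", "atac", "genome", "variants"),
  integration = c("genes", "tf1", "orthogroups", "expression"),
  predictor = c("genes", "tf1", "expression", "dap"),
  duplication = c("genes", "tf1", "expression", "duplicate_pairs",
                  "tissue_expression"))

.write_tsv_report <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline from a config
#'
#' Validates the config, checks that every requested stage has its inputs
#' (failing with a named error before any computation), then runs the stages
#' in dependency order and writes one report file per stage plus a run log.
#' Every output carries the config hash; outputs are deterministic given the
#' config (including its seed).
#'
#' @param config a config list ([pipeline_config()]) or the path to a YAML
#'   file with the same structure.
#' @param out_dir report directory (created if needed).
#' @return invisibly, a named list of the in-memory stage results.
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("species", "focal", "windows", "stages", "inputs", "seed"))
    if (is.null(config[[field]])) stop("config is missing field: ", field)
  species <- unlist(config$species)
  focal <- config$focal
  if (!focal %in% species) stop("focal species not in species list")
  stages <- unlist(config$stages)
  unknown <- setdiff(stages, names(.stage_requirements))
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  ## validate inputs for every requested stage before computing anything
  for (st in stages) {
    need <- .stage_requirements[[st]]
    miss <- need[vapply(need, function(k) is.null(config$inputs[[k]]), TRUE)]
    if (length(miss))
      stop("stage '", st, "' requested but input(s) missing: ",
           paste(miss, collapse = ", "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  res <- list(config_hash = hash)
  idr_max <- if (is.null(config$idr_max)) 0.01 else config$idr_max
  signal_min <- if (is.null(config$signal_min)) 0 else config$signal_min
  flank <- if (is.null(config$summit_flank)) 75L else as.integer(config$summit_flank)

  ## --- targets ------------------------------------------------------------
  genes <- lapply(config$inputs$genes, read_gene_table)
  assignments <- list(); targets <- list(); tf_peaks <- list()
  if (any(c("targets", "conservation", "kmer", "diversity", "integration",
            "predictor", "duplication") %in% stages)) {
    for (s in intersect(species, names(config$inputs$tf1))) {
      pk <- suppressMessages(
        filter_peaks(read_narrowpeak(config$inputs$tf1[[s]]),
                     idr_max = idr_max, signal_min = signal_min))
      tf_peaks[[s]] <- pk
      asn <- assign_peaks_to_genes(pk, genes[[s]],
                                   as.integer(config$windows[[s]]))
      if (!is.null(config$inputs$tf2[[s]])) {
        pk2 <- read_narrowpeak(config$inputs$tf2[[s]])
        asn$signal_fc2 <- pk2$signal_fc[match(asn$peak, pk2$name)]
        asn$signal_fc2[is.na(asn$signal_fc2)] <- asn$signal_fc[is.na(asn$signal_fc2)]
      }
      assignments[[s]] <- asn
      targets[[s]] <- unique(asn$gene_id)
      .write_tsv_report(asn, file.path(out_dir, paste0("targets_", s, ".tsv")),
                        hash)
    }
    res$assignments <- assignments
    res$targets <- targets
  }

  ## --- conservation -------------------------------------------------------
  if (any(c("conservation", "integration", "diversity") %in% stages)) {
    orth <- read_orthogroups(config$inputs$orthogroups, species)
    cons <- conservation_levels(targets, orth, focal)
    res$conservation <- cons
    lv <- data.frame(gene_id = names(cons$levels),
                     conservation_level = unname(cons$levels))
    .write_tsv_report(lv, file.path(out_dir, "conservation.tsv"), hash)
    cats <- unique(genes[[focal]]$category)
    cat_scores <- vapply(sort(cats[!is.na(cats)]), function(cc) {
      cat_genes <- lapply(species, function(s) {
        g <- genes[[s]]
        intersect(targets[[s]], g$gene_id[g$category == cc])
      })
      names(cat_genes) <- species
      if (!any(lengths(cat_genes) > 0)) return(NA_real_)
      tryCatch(conservation_score(cat_genes, orth, species),
               error = function(e) NA_real_)   # e.g. only unplaced targets
    }, 0)
    pair2 <- two_species_groups(targets[[focal]], targets[[species[[2]]]],
                                orth, focal, species[[2]])
    jsonlite::write_json(
      list(config_hash = hash,
           groups = as.list(stats::setNames(as.integer(cons$groups),
                                            names(cons$groups))),
           n_targets = length(cons$levels), n_unplaced = cons$n_unplaced,
           category_scores = as.list(cat_scores),
           two_species = lapply(pair2, length)),
      file.path(out_dir, "conservation_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  ## --- k-mer model ---------------------------------------------------------
  if ("kmer" %in% stages) {
    genome <- Biostrings::readDNAStringSet(config$inputs$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    kcfg <- config$kmer
    pos <- suppressWarnings(extract_windows(tf_peaks[[focal]],
                                            as.integer(kcfg$width), genome))
    atac <- read_narrowpeak(config$inputs$atac[[focal]])
    ds <- build_balanced_dataset(pos, atac, genome,
                                 weak_peaks = tf_peaks[[focal]],
                                 width = as.integer(kcfg$width), seed = seed)
    km <- train_bag_of_kmers(ds, k = as.integer(kcfg$k),
                             test_frac = kcfg$test_frac, seed = seed)
    res$kmer <- km
    jsonlite::write_json(
      list(config_hash = hash, k = km$k, auc = km$auc, acc = km$acc,
           top_kmers = km$top_kmers),
      file.path(out_dir, "kmer_model.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  ## --- motif diversity -----------------------------------------------------
  if ("diversity" %in% stages) {
    if (!exists("genome", inherits = FALSE)) {
      genome <- Biostrings::readDNAStringSet(config$inputs$genome)
      names(genome) <- sub("\\s.*$", "", names(genome))
    }
    motif <- if (is.null(config$motif)) "RGATTYY" else config$motif
    hits <- scan_iupac(genome, motif)
    atac <- read_narrowpeak(config$inputs$atac[[focal]])
    hits <- classify_motif_sites(hits, tf_peaks[[focal]], atac)
    panel <- read_variant_table(config$inputs$variants)
    keep <- hits$klass != "excluded"
    sd_tab <- motif_diversity(hits[keep, , drop = FALSE], panel)
    res$diversity <- sd_tab
    contrast <- diversity_contrast(sd_tab, "bound", "unbound_background",
                                   exact = FALSE)
    res$diversity_test <- contrast
    .write_tsv_report(sd_tab, file.path(out_dir, "diversity.tsv"), hash)
    jsonlite::write_json(c(list(config_hash = hash), contrast),
                         file.path(out_dir, "diversity_tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  ## --- expression integration ---------------------------------------------
  if (any(c("integration", "predictor", "duplication") %in% stages)) {
    expr <- utils::read.delim(config$inputs$expression, stringsAsFactors = FALSE)
    for (col in c("is_deg", "is_down"))
      if (col %in% names(expr)) expr[[col]] <- as.logical(expr[[col]])
  }
  if ("integration" %in% stages) {
    ov <- summarize_deg_overlap(targets[[focal]], expr)
    rate <- deg_rate_by_conservation(res$conservation, expr)
    strength <- binding_strength_by_group(assignments[[focal]],
                                          res$conservation)
    volcano <- volcano_join(expr, assignments[[focal]], res$conservation)
    res$integration <- list(deg_overlap = ov, deg_rate = rate,
                            binding_strength = strength)
    .write_tsv_report(volcano, file.path(out_dir, "integrated.tsv"), hash)
    jsonlite::write_json(
      list(config_hash = hash, deg_overlap = ov,
           deg_rate = rate, kruskal_H = strength$H, kruskal_p = strength$p),
      file.path(out_dir, "integration.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  ## --- DEG predictor --------------------------------------------------------
  if ("predictor" %in% stages) {
    dap <- lapply(config$inputs$dap, read_narrowpeak)
    feats <- suppressMessages(
      assemble_features(assignments[[focal]], expr, dap, genes[[focal]],
                        summit_flank = flank))
    pcfg <- config$predictor
    feats <- suppressMessages(
      filter_cobinding_features(feats, r_min = pcfg$r_min))
    mm <- resample_train(feats, n_models = as.integer(pcfg$n_models),
                         seed = seed, num_trees = as.integer(pcfg$num_trees))
    abl <- ablation(feats, n_models = as.integer(pcfg$n_models), seed = seed,
                    num_trees = as.integer(pcfg$num_trees), full = mm)
    imp <- mean_importance(mm)
    res$predictor <- list(metrics = mm, ablation = abl, importance = imp)
    .write_tsv_report(imp, file.path(out_dir, "importance.tsv"), hash)
    .write_tsv_report(abl, file.path(out_dir, "ablation.tsv"), hash)
    jsonlite::write_json(
      list(config_hash = hash, n_models = mm$n_models,
           means = as.list(mm$means), sds = as.list(mm$sds)),
      file.path(out_dir, "predictor_metrics.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }

  ## --- duplication -----------------------------------------------------------
  if ("duplication" %in% stages) {
    pairs <- utils::read.delim(config$inputs$duplicate_pairs,
                               stringsAsFactors = FALSE)
    pairs <- suppressMessages(classify_retention(pairs, targets[[focal]]))
    cl <- assignments[[focal]][assignments[[focal]]$closest, , drop = FALSE]
    sig <- stats::setNames(cl$signal_fc, cl$gene_id)
    pairs$signal_a <- unname(sig[pairs$gene_a])
    pairs$signal_b <- unname(sig[pairs$gene_b])
    both <- pairs[pairs$retention == "both", , drop = FALSE]
    conc <- if (nrow(both) >= 3L) signal_concordance(both) else
      list(tau = NA_real_, p = NA_real_, n = nrow(both))
    tis <- utils::read.delim(config$inputs$tissue_expression,
                             stringsAsFactors = FALSE, check.names = FALSE)
    em <- as.matrix(tis[, -1, drop = FALSE])
    rownames(em) <- tis[[1]]
    ec <- suppressMessages(expression_correlation_by_retention(pairs, em))
    res$duplication <- list(concordance = conc, expression = ec)
    jsonlite::write_json(
      list(config_hash = hash, kendall_tau = conc$tau, kendall_p = conc$p,
           n_both = conc$n, class_mean_corr = as.list(ec$class_means),
           t_both_vs_none = ec$t_both_vs_none,
           p_both_vs_none = ec$p_both_vs_none),
      file.path(out_dir, "duplication.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  ## --- run log ---------------------------------------------------------------
  outs <- sort(list.files(out_dir))
  outs <- setdiff(outs, "run_log.json")
  jsonlite::write_json(
    list(config_hash = hash, seed = seed,
         package_version = as.character(utils::packageVersion("cistromediv")),
         stages = stages, outputs = outs),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(res)
}
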