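## Cross-species conservation of target genes: per-gene conservation levels,
## category conservation scores, two-species group partitions, enrichment
## tests and threshold-robustness tables.

# map gene_id -> orthogroup id for fast lookup
.og_index <- function(orthology) {
  genes <- unlist(orthology, use.names = FALSE)
  reps <- vapply(orthology, function(og) length(unlist(og, use.names = FALSE)), 1L)
  stats::setNames(rep(names(orthology), reps), genes)
}

#' Conservation levels of focal-species target genes
#'
#' For every target gene of the focal species, the conservation level is the
#' number of species (focal included) whose members of the gene's orthogroup
#' include at least one target. Genes placed in no orthogroup count as level 1
#' (species-specific); they are reported in `n_unplaced`.
#'
#' @param targets_by_species named list (species -> character vector of target
#'   gene ids).
#' @param orthology orthogroup list from [read_orthogroups()].
#' @param focal name of the focal species (must be in `targets_by_species`).
#' @return list with `levels` (named integer vector over focal targets),
#'   `groups` (table of group sizes 1..S), `n_unplaced`, `S`.
#' @export
conservation_levels <- function(targets_by_species, orthology, focal) {
  if (!focal %in% names(targets_by_species))
    stop("focal species not in targets_by_species")
  species <- names(targets_by_species)
  S <- length(species)
  idx <- .og_index(orthology)
  focal_targets <- unique(targets_by_species[[focal]])
  og_of <- idx[focal_targets]
  ## per relevant orthogroup: number of species with >= 1 target in it
  ogs <- unique(stats::na.omit(og_of))
  n_bound <- vapply(ogs, function(ogid) {
    og <- orthology[[ogid]]
    sum(vapply(species, function(s)
      any(og[[s]] %in% targets_by_species[[s]]), TRUE))
  }, 1L)
  names(n_bound) <- ogs
  lev <- ifelse(is.na(og_of), 1L, n_bound[og_of])
  names(lev) <- focal_targets
  lev[lev < 1L] <- 1L
  groups <- table(factor(lev, levels = seq_len(S)))
  list(levels = lev, groups = groups, n_unplaced = sum(is.na(og_of)), S = S)
}

#' Conservation score of a gene category
#'
#' Quantifies how conserved a category's targeting is from observed
#' cross-species sharing events relative to the pairwise comparisons
#' performed:
#' `score = sum_og (# species pairs both targeting the category in og) /
#' (N_og * choose(S, 2))`, with `N_og` the number of orthogroups holding at
#' least one category target in at least one species. Equals 1 iff every such
#' orthogroup is targeted in all species.
#'
#' @param category_genes named list (species -> gene ids in the category that
#'   are targets).
#' @param orthology orthogroup list.
#' @param species species vector defining the comparisons (defaults to
#'   `names(category_genes)`).
#' @return score in `[0, 1]`.
#' @export
conservation_score <- function(category_genes, orthology,
                               species = names(category_genes)) {
  S <- length(species)
  if (S < 2L) stop("need at least two species")
  idx <- .og_index(orthology)
  ogs <- unique(stats::na.omit(unlist(lapply(species, function(s)
    idx[category_genes[[s]]]), use.names = FALSE)))
  if (!length(ogs)) stop("no category targets found in any orthogroup")
  events <- vapply(ogs, function(og) {
    hit <- vapply(species, function(s)
      length(intersect(orthology[[og]][[s]], category_genes[[s]])) > 0L, TRUE)
    choose(sum(hit), 2)
  }, 0)
  sum(events) / (length(ogs) * choose(S, 2))
}

#' Two-species conserved / species-specific target groups
#'
#' Partitions the orthogroups holding any target of either species into
#' group I (targeted in both), group II (A-specific) and group III
#' (B-specific).
#'
#' @param targetsA,targetsB target gene-id vectors of the two species.
#' @param orthology orthogroup list.
#' @param speciesA,speciesB the two species' names as used in `orthology`.
#' @return list of orthogroup-id vectors `I`, `II`, `III` (disjoint,
#'   exhaustive over target orthogroups).
#' @export
two_species_groups <- function(targetsA, targetsB, orthology,
                               speciesA, speciesB) {
  inA <- vapply(orthology, function(og)
    length(intersect(og[[speciesA]], targetsA)) > 0L, TRUE)
  inB <- vapply(orthology, function(og)
    length(intersect(og[[speciesB]], targetsB)) > 0L, TRUE)
  list(I = names(orthology)[inA & inB],
       II = names(orthology)[inA & !inB],
       III = names(orthology)[!inA & inB])
}

#' Functional-category enrichment among target genes
#'
#' Per category, a 2x2 table (target / non-target x in / out of category) is
#' tested with Fisher's exact test (two-sided) and corrected across
#' categories by Benjamini-Hochberg.
#'
#' @param targets target gene ids (subset of `universe`).
#' @param universe all gene ids.
#' @param categories named factor/character vector over `universe` giving each
#'   gene's category label.
#' @return data.frame: `category`, `n_target_in`, `n_target_out`, `n_bg_in`,
#'   `n_bg_out`, `odds_ratio`, `p`, `q`.
#' @export
category_enrichment <- function(targets, universe, categories) {
  if (!all(targets %in% universe)) stop("targets must be a subset of universe")
  if (is.null(names(categories)) || !all(universe %in% names(categories)))
    stop("categories must be named over the universe")
  cats <- sort(unique(as.character(categories[universe])))
  is_t <- universe %in% targets
  rows <- lapply(cats, function(cc) {
    in_c <- categories[universe] == cc
    a <- sum(is_t & in_c); b <- sum(is_t & !in_c)
    c_ <- sum(!is_t & in_c); d <- sum(!is_t & !in_c)
    ft <- stats::fisher.test(matrix(c(a, c_, b, d), 2L), alternative = "two.sided")
    data.frame(category = cc, n_target_in = a, n_target_out = b,
               n_bg_in = c_, n_bg_out = d,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Conservation robustness across peak-calling stringencies
#'
#' For target sets derived at increasing stringency, reports the target count
#' and the conservation rate (fraction of focal targets at level >= 2). A
#' robust conservation analysis shows rates that stay flat or decline as the
#' threshold is raised.
#'
#' @param targets_by_threshold named list (threshold label -> list of
#'   per-species target sets, as in [conservation_levels()]), ordered from
#'   least to most stringent.
#' @param orthology orthogroup list.
#' @param focal focal species.
#' @return data.frame: `threshold`, `n_targets`, `conservation_rate`.
#' @export
conservation_robustness <- function(targets_by_threshold, orthology, focal) {
  if (length(targets_by_threshold) < 2L) stop("need >= 2 thresholds")
  rows <- lapply(names(targets_by_threshold), function(th) {
    cl <- conservation_levels(targets_by_threshold[[th]], orthology, focal)
    data.frame(threshold = th, n_targets = length(cl$levels),
               conservation_rate = mean(cl$levels >= 2L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Quantitative signal comparison of homologous gene pairs
#'
#' Pairs each focal gene with a homolog in the other species through the
#' orthology map and compares binding signal quantitatively. Many-to-many
#' orthogroups are collapsed to the best-signal representative on each side
#' (logged via message).
#'
#' @param signalA,signalB named numeric vectors (gene id -> signal) for the
#'   two species.
#' @param orthology orthogroup list.
#' @param speciesA,speciesB species names as used in `orthology`.
#' @return list with `pairs` (data.frame `orthogroup`, `gene_a`, `gene_b`,
#'   `signal_a`, `signal_b`, `call` in conserved/A_specific/B_specific) and
#'   Pearson `r` over pairs with both signals.
#' @export
quantitative_homolog_comparison <- function(signalA, signalB, orthology,
                                            speciesA, speciesB) {
  if (!length(orthology)) stop("empty orthology map")
  best <- function(genes, sig) {
    g <- genes[genes %in% names(sig)]
    if (!length(g)) return(NA_character_)
    g[which.max(sig[g])]
  }
  rows <- lapply(names(orthology), function(og) {
    ga <- orthology[[og]][[speciesA]]; gb <- orthology[[og]][[speciesB]]
    if (!length(ga) || !length(gb)) return(NULL)
    a <- best(ga, signalA); b <- best(gb, signalB)
    data.frame(orthogroup = og,
               gene_a = if (is.na(a)) ga[[1]] else a,
               gene_b = if (is.na(b)) gb[[1]] else b,
               signal_a = if (is.na(a)) 0 else unname(signalA[a]),
               signal_b = if (is.na(b)) 0 else unname(signalB[b]),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) < 3L) stop("fewer than 3 homologous pairs")
  n_multi <- sum(vapply(orthology, function(og)
    length(og[[speciesA]]) > 1L || length(og[[speciesB]]) > 1L, TRUE))
  if (n_multi) message(n_multi, " many-to-many orthogroup(s) collapsed to best-signal representatives")
  pairs$call <- ifelse(pairs$signal_a > 0 & pairs$signal_b > 0, "conserved",
                       ifelse(pairs$signal_a > 0, "A_specific", "B_specific"))
  both <- pairs$signal_a > 0 & pairs$signal_b > 0
  r <- if (sum(both) >= 3L) stats::cor(pairs$signal_a[both], pairs$signal_b[both]) else NA_real_
  list(pairs = pairs, r = r)
}
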