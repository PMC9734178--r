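## Nucleotide diversity of motif instances and one-sided ECDF / K-S contrasts
## between site classes (bound vs unbound background, conserved vs not,
## DEG vs non-DEG).

#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity
#' `pi = n/(n-1) * (1 - sum(p_k^2))` from allele frequencies `p` over `n`
#' sampled haplotypes. Sites carrying a precomputed `pi` are passed through
#' unchanged by [motif_diversity()].
#'
#' @param freqs numeric allele frequencies summing to 1.
#' @param n_haplotypes number of haplotypes sampled (>= 2).
#' @return nucleotide diversity, a nonnegative real.
#' @examples
#' site_pi(c(0.5, 0.5), 10)   # 10/9 * 0.5
#' @export
site_pi <- function(freqs, n_haplotypes) {
  n <- as.numeric(n_haplotypes)
  if (n < 2) stop("n_haplotypes must be >= 2")
  if (abs(sum(freqs) - 1) > 1e-6) stop("allele frequencies must sum to 1")
  n / (n - 1) * (1 - sum(freqs^2))
}

#' Nucleotide diversity of motif hits
#'
#' For each motif hit, averages per-position diversity over the motif
#' positions. Positions absent from the variant panel are invariant in the
#' population sample and contribute `pi = 0`; excluding them would bias the
#' motif mean upward for sparsely covered motifs.
#'
#' @param hits hits data.frame ([scan_iupac()] output, `seq_id` = chromosome).
#' @param panel variant panel from [read_variant_table()].
#' @return `hits` with a `motif_pi` column (mean per-position diversity).
#' @export
motif_diversity <- function(hits, panel) {
  pi_site <- panel$pi
  need <- is.na(pi_site)
  pi_site[need] <- mapply(site_pi, panel$freqs[need], panel$n_haplotypes[need])
  key <- paste(panel$chrom, panel$pos)
  lookup <- stats::setNames(pi_site, key)
  hits$motif_pi <- vapply(seq_len(nrow(hits)), function(i) {
    pos <- hits$start[i]:(hits$end[i] - 1L)
    v <- lookup[paste(hits$seq_id[i], pos)]
    v[is.na(v)] <- 0
    mean(v)
  }, 0)
  hits
}

# ECDF sanity: right-continuous step function reaching 1
.check_ecdf <- function(x) {
  F <- stats::ecdf(x)
  v <- F(sort(unique(x)))
  stopifnot(!is.unsorted(v), abs(v[length(v)] - 1) < 1e-12)
  invisible(F)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether sample A is stochastically smaller than sample B using
#' `D+ = sup_x (F_A(x) - F_B(x))`. The p-value is the one-sided asymptotic
#' form `exp(-2 D+^2 m n / (m + n))`; for `m + n <= 20` an exact permutation
#' p-value over all label reassignments can be requested (or is used by
#' default when `exact = NULL`).
#'
#' @param sampleA,sampleB numeric samples (nonempty).
#' @param alternative only `"A_less"` (A stochastically smaller, i.e. its ECDF
#'   lies above B's).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the permutation p-value;
#'   `NULL` = automatic for `m + n <= 20`.
#' @param n_perm number of permutations when sampling (exhaustive enumeration
#'   is used when the number of distinct label assignments is below this).
#' @return list with statistic `D` and `p`.
#' @export
ks_one_sided <- function(sampleA, sampleB, alternative = "A_less",
                         exact = NULL, n_perm = 20000L) {
  alternative <- match.arg(alternative, "A_less")
  if (!length(sampleA) || !length(sampleB)) stop("empty sample")
  m <- length(sampleA); n <- length(sampleB)
  FA <- .check_ecdf(sampleA); FB <- .check_ecdf(sampleB)
  grid <- sort(unique(c(sampleA, sampleB)))
  dplus <- function(a, b) {
    Fa <- stats::ecdf(a); Fb <- stats::ecdf(b)
    max(Fa(grid) - Fb(grid))
  }
  D <- max(FA(grid) - FB(grid))
  if (is.null(exact)) exact <- (m + n) <= 20L
  if (exact) {
    pool <- c(sampleA, sampleB)
    if (choose(m + n, m) <= n_perm) {
      combs <- utils::combn(m + n, m)
      stats_perm <- apply(combs, 2L, function(idx) dplus(pool[idx], pool[-idx]))
    } else {
      stats_perm <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(m + n, m)
        dplus(pool[idx], pool[-idx])
      }, 0)
    }
    p <- mean(stats_perm >= D - 1e-12)
  } else {
    p <- min(1, exp(-2 * D^2 * m * n / (m + n)))
  }
  list(D = D, p = p)
}

#' Compare motif diversity between two site classes
#'
#' Convenience wrapper running [ks_one_sided()] on the `motif_pi` values of
#' two `klass` labels, testing whether the first class (e.g. `bound`) has
#' stochastically smaller diversity than the second (e.g.
#' `unbound_background`) — the signature of purifying selection on bound
#' sites.
#'
#' @param site_div output of [motif_diversity()] with a `klass` column.
#' @param class_a,class_b the two class labels to compare (A tested smaller).
#' @param ... passed to [ks_one_sided()].
#' @return list with `D`, `p`, per-class `n` and mean diversity.
#' @export
diversity_contrast <- function(site_div, class_a = "bound",
                               class_b = "unbound_background", ...) {
  a <- site_div$motif_pi[site_div$klass == class_a]
  b <- site_div$motif_pi[site_div$klass == class_b]
  ks <- ks_one_sided(a, b, ...)
  list(D = ks$D, p = ks$p, n_a = length(a), n_b = length(b),
       mean_a = mean(a), mean_b = mean(b))
}
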