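make_orthology <- function(...) {
  # make_orthology(og1 = list(A = "a1", B = "b1"), ...)
  list(...)
}

test_that("conservation levels count species with targets in the orthogroup", {
  orth <- make_orthology(
    OG1 = list(A = "a1", B = "b1", C = "c1"),
    OG2 = list(A = "a2", B = "b2", C = "c2"),
    OG3 = list(A = "a3", B = character(), C = "c3"))
  targets <- list(A = c("a1", "a2", "zz_unplaced"), B = "b1", C = character())
  cl <- conservation_levels(targets, orth, focal = "A")
  expect_equal(unname(cl$levels[c("a1", "a2", "zz_unplaced")]), c(2L, 1L, 1L))
  expect_equal(as.integer(cl$groups), c(2L, 1L, 0L))
  expect_equal(cl$n_unplaced, 1L)
  # partition invariant: group sizes sum to the focal target count
  expect_equal(sum(cl$groups), length(cl$levels))
})

test_that("conservation score is shared-pair events over pairwise comparisons", {
  orth <- make_orthology(OG1 = list(A = "a1", B = "b1"))
  expect_equal(conservation_score(list(A = "a1", B = "b1"), orth), 1.0)
  orth3 <- make_orthology(OG1 = list(A = "a1", B = "b1", C = "c1"))
  # bound in exactly 2 of 3 species: 1 concordant pair of C(3,2) = 3
  expect_equal(conservation_score(list(A = "a1", B = "b1", C = character()),
                                  orth3, species = c("A", "B", "C")), 1 / 3)
  # a single-species orthogroup contributes zero to the numerator
  orth2 <- make_orthology(OG1 = list(A = "a1", B = "b1"),
                          OG2 = list(A = "a2", B = "b2"))
  expect_equal(conservation_score(list(A = c("a1", "a2"), B = "b1"), orth2),
               1 / 2)
  expect_error(conservation_score(list(A = "qq", B = character()), orth2),
               "no category targets")
  # score is 1 iff every category orthogroup is targeted in all species
  expect_equal(conservation_score(list(A = c("a1", "a2"), B = c("b1", "b2")),
                                  orth2), 1.0)
})

test_that("two-species groups partition the target orthogroups", {
  orth <- make_orthology(OG1 = list(A = "a1", B = "b1"),
                         OG2 = list(A = "a2", B = "b2"),
                         OG3 = list(A = "a3", B = "b3"),
                         OG4 = list(A = "a4", B = "b4"))
  gr <- two_species_groups(c("a1", "a2"), c("b1", "b3"), orth, "A", "B")
  expect_equal(gr$I, "OG1")
  expect_equal(gr$II, "OG2")
  expect_equal(gr$III, "OG3")
  expect_equal(length(gr$I) + length(gr$II) + length(gr$III), 3L)
})

test_that("category enrichment reproduces the exact hypergeometric two-sided p", {
  universe <- sprintf("g%d", 1:8)
  categories <- stats::setNames(rep(c("X", "Y"), each = 4), universe)
  targets <- c("g1", "g2", "g3", "g5")   # 2x2 table [[3,1],[1,3]]
  enr <- category_enrichment(targets, universe, categories)
  expect_equal(enr$p[enr$category == "X"], 34 / 70)
  # single category spanning the universe is never enriched
  cat1 <- stats::setNames(rep("X", 8), universe)
  expect_equal(category_enrichment(targets, universe, cat1)$p, 1)
  expect_error(category_enrichment("nope", universe, categories), "subset")
})

test_that("Fisher p agrees with a label-permutation estimate on a small table", {
  universe <- sprintf("g%d", 1:12)
  categories <- stats::setNames(rep(c("X", "Y"), c(5, 7)), universe)
  targets <- c("g1", "g2", "g3", "g4", "g6")
  p_exact <- category_enrichment(targets, universe,
                                 categories)$p[1]
  set.seed(13)
  n_in_cat <- function(t) sum(t %in% universe[categories == "X"])
  obs <- n_in_cat(targets)
  probs <- table(replicate(20000, n_in_cat(sample(universe, length(targets)))))
  probs <- probs / sum(probs)
  p_perm <- sum(probs[as.numeric(probs) <= probs[[as.character(obs)]] + 1e-12])
  expect_equal(p_exact, p_perm, tolerance = 0.05)
})

test_that("robustness tables track target counts and conservation rate", {
  orth <- make_orthology(OG1 = list(A = "a1", B = "b1"),
                         OG2 = list(A = "a2", B = "b2"))
  loose <- list(A = c("a1", "a2"), B = "b1")
  strict <- list(A = "a1", B = "b1")     # stringency removes the A-specific one
  tab <- conservation_robustness(list(loose = loose, strict = strict),
                                 orth, focal = "A")
  expect_equal(tab$n_targets, c(2L, 1L))          # nonincreasing
  expect_equal(tab$conservation_rate, c(0.5, 1))  # rate rises, no error
  # identical target sets at both thresholds give identical rates
  tab2 <- conservation_robustness(list(t1 = loose, t2 = loose), orth, "A")
  expect_equal(tab2$conservation_rate[1], tab2$conservation_rate[2])
  expect_error(conservation_robustness(list(only = loose), orth, "A"), ">= 2")
})

test_that("homolog signal comparison pairs best representatives", {
  orth <- make_orthology(OG1 = list(A = "a1", B = "b1"),
                         OG2 = list(A = c("a2", "a2b"), B = "b2"),
                         OG3 = list(A = "a3", B = "b3"))
  sigA <- c(a1 = 5, a2 = 1, a2b = 9, a3 = 4)
  sigB <- c(b1 = 5, b2 = 9, b3 = 4)
  out <- suppressMessages(
    quantitative_homolog_comparison(sigA, sigB, orth, "A", "B"))
  expect_equal(out$pairs$gene_a[out$pairs$orthogroup == "OG2"], "a2b")
  expect_equal(out$r, 1)                 # identical signals after collapsing
  expect_error(quantitative_homolog_comparison(sigA, sigB, list(), "A", "B"),
               "empty orthology")
})

test_that("recovered conservation levels equal the planted ground truth exactly", {
  co <- small_cohort()
  species <- co$config$species
  orth <- read_orthogroups(co$paths$orthogroups, species)
  targets <- lapply(species, function(s) {
    pk <- read_narrowpeak(co$paths[[paste0("tf1_", s)]])
    genes <- read_gene_table(co$paths[[paste0("genes_", s)]])
    unique(assign_peaks_to_genes(pk, genes,
                                 co$config$promoter_window_bp[[s]])$gene_id)
  })
  names(targets) <- species
  cl <- conservation_levels(targets, orth, species[[1]])
  truth <- co$truth$focal_target_levels
  expect_setequal(names(cl$levels), names(truth))
  expect_equal(unname(cl$levels[names(truth)]), unname(truth))
})

test_that("a fully conserved configuration yields 100% level-S targets", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_orthogroups = 60L, frac_conserved = 1,
                       n_duplicate_pairs = 18L, n_unplaced = 0L, seed = 5L)
  co <- generate_cohort(cfg, dir)
  species <- cfg$species
  orth <- read_orthogroups(co$paths$orthogroups, species)
  cl <- conservation_levels(co$truth$targets_by_species, orth, species[[1]])
  expect_true(all(cl$levels == cfg$n_species))
})
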