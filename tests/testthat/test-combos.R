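test_that("expression gate is strict and deterministic", {
  expr <- data.frame(gene = c("A", "B", "C", "D", "E"),
                     mean_rsem = c(500, 200, 199, 201, 10000),
                     stringsAsFactors = FALSE)
  cfg <- combo_config()
  out <- eligible_genes(expr, c("A", "B", "C", "D", "E"), cfg)
  expect_equal(out, c("A", "D", "E"))  # 200 itself is excluded

  cfg0 <- combo_config(expression_threshold = 0)
  expect_equal(eligible_genes(expr, c("A", "C"), cfg0), c("A", "C"))

  expect_warning(eligible_genes(expr, c("A", "ZZ"), cfg), "missing")
  expect_error(
    suppressWarnings(eligible_genes(expr, "ZZ", cfg)), "threshold")
})

test_that("candidate enumeration counts subsets and applies the prevalence rule", {
  samples <- sprintf("s%02d", 1:20)
  rec <- data.frame(
    gene = c("A", "B", "C"), sample = c("s01", "s01", "s02"),
    variant_class = rep("Missense_Mutation", 3), stringsAsFactors = FALSE)
  m <- build_mutation_matrix(rec, samples, c("A", "B", "C"))
  cfg <- combo_config(prevalence_threshold = 0.05)
  cand <- enumerate_candidates(c("A", "B", "C"), m, cfg, sizes = 2L)
  # C(3,2) = 3 pairs; every pair is mutated in >= 1/20 = 5% of samples,
  # which meets the inclusive >= threshold
  expect_equal(length(cand$sets), 3)
  expect_true(all(cand$prevalence >= 0.05))

  # the pair {A,B}, mutated in exactly 1 of 20 samples (5%), is retained
  expect_true(any(vapply(cand$sets, identical, logical(1), c("A", "B"))))

  # raising the bar drops the 5% pair but keeps the two 10% pairs
  cfg2 <- combo_config(prevalence_threshold = 0.08)
  cand2 <- enumerate_candidates(c("A", "B", "C"), m, cfg2, sizes = 2L)
  expect_equal(length(cand2$sets), 2)
  expect_true(all(cand2$n_mutated == 2L))

  # never-mutated subsets are dropped
  m0 <- build_mutation_matrix(rec[0, ], samples, c("A", "B", "C"))
  cand0 <- enumerate_candidates(c("A", "B", "C"), m0, cfg, sizes = 2L)
  expect_equal(length(cand0$sets), 0)
})

test_that("superset exclusion removes size-3 sets containing flagged pairs", {
  samples <- sprintf("s%02d", 1:10)
  rec <- data.frame(gene = rep(c("A", "B", "C", "D"), each = 5),
                    sample = rep(samples[1:5], 4),
                    variant_class = "Missense_Mutation",
                    stringsAsFactors = FALSE)
  m <- build_mutation_matrix(rec, samples, c("A", "B", "C", "D"))
  cfg <- combo_config()
  all3 <- enumerate_candidates(c("A", "B", "C", "D"), m, cfg, sizes = 3L)
  expect_equal(length(all3$sets), choose(4, 3))
  excl <- enumerate_candidates(c("A", "B", "C", "D"), m, cfg, sizes = 3L,
                               exclude_supersets_of = list(c("A", "B")))
  expect_equal(length(excl$sets), choose(4, 3) - 2)  # ABC and ABD dropped
  expect_false(any(vapply(excl$sets,
                          function(s) all(c("A", "B") %in% s), logical(1))))
})

test_that("background draws always land inside the tolerance window", {
  co <- make_null_cohort(seed = 37, n_samples = 150, n_genes = 120)
  prof <- profiles_of(co, classes = c("missense", "truncation"))
  pool <- prof[!prof$in_family, ]
  set.seed(101)
  for (i in 1:200) {
    target <- sample(20:120, 1)
    draw <- sample_background(pool, target, tolerance = 5)
    expect_true(draw$total_mutations >= target - 5 &&
                draw$total_mutations <= target + 5)
    expect_equal(sum(pool$n_mutations[match(draw$genes, pool$gene)]),
                 draw$total_mutations)
    expect_false(anyDuplicated(draw$genes) > 0)
  }
  # unreachable window errors out: the smallest gene count overshoots
  tiny <- data.frame(gene = c("a", "b"), n_mutations = c(5L, 7L),
                     stringsAsFactors = FALSE)
  expect_error(sample_background(tiny, 1, tolerance = 0, max_retries = 20),
               "window")
  # a target equal to one gene's exact count at tolerance 0 is valid
  one <- sample_background(tiny, 5, tolerance = 0)
  expect_equal(one$total_mutations, 5L)
})

test_that("q-values are monotone in p and the scan is seed-deterministic", {
  co <- simulate_cohort(sim_config(
    n_samples = 200, n_genes = 150, n_family_genes = 8,
    gene_length_range = c(3000, 4000), mut_rate_mss = 6, mut_rate_msih = 40,
    seed = 41))
  cfg <- combo_config(n_background = 150, seed = 9)
  sc1 <- combo_scan(co$maf, co$clinical, co$expression, co$genes,
                    config = cfg)
  sc2 <- combo_scan(co$maf, co$clinical, co$expression, co$genes,
                    config = cfg)
  expect_identical(sc1$results, sc2$results)

  r <- sc1$results[order(sc1$results$logrank_p), ]
  for (k in unique(r$size)) {
    q <- r$q_value[r$size == k]
    expect_true(all(diff(q) >= -1e-12))
  }
  expect_true(all(r$q_value >= 0 & r$q_value <= 1))
  expect_equal(r$prevalence, r$n_mutated / 200)
})

test_that("removing the exclusion rule never decreases size-3 candidates", {
  co <- simulate_cohort(sim_config(
    n_samples = 200, n_genes = 150, n_family_genes = 8,
    gene_length_range = c(3000, 4000), mut_rate_mss = 6, mut_rate_msih = 40,
    effect_sets = list(list(genes = c(1, 2), log_hr = log(0.3))),
    seed = 43))
  cfg_on <- combo_config(n_background = 150, seed = 9,
                         exclude_significant_subsets = TRUE)
  cfg_off <- combo_config(n_background = 150, seed = 9,
                          exclude_significant_subsets = FALSE)
  sc_on <- combo_scan(co$maf, co$clinical, co$expression, co$genes,
                      config = cfg_on)
  sc_off <- combo_scan(co$maf, co$clinical, co$expression, co$genes,
                       config = cfg_off)
  expect_lte(sum(sc_on$results$size == 3), sum(sc_off$results$size == 3))
})

test_that("inclusion frequencies count gene appearances by direction", {
  res <- data.frame(
    genes = c("A,B", "A,C", "B,D", "A,E"),
    size = c(2L, 2L, 2L, 2L),
    n_mutated = c(5L, 5L, 5L, 5L),
    prevalence = rep(0.1, 4),
    total_mutations = rep(10L, 4),
    logrank_p = c(0.001, 0.002, 0.2, 0.01),
    direction = c("longer_OS", "longer_OS", "longer_OS", "shorter_OS"),
    q_value = c(0.01, 0.02, 0.5, 0.04),
    stringsAsFactors = FALSE
  )
  attr(res, "sets") <- list(c("A", "B"), c("A", "C"), c("B", "D"),
                            c("A", "E"))
  inc <- inclusion_frequencies(res, q_threshold = 0.05)
  longer <- inc[inc$direction == "longer_OS", ]
  expect_equal(longer$n_combinations[longer$gene == "A"], 2L)
  expect_equal(longer$n_combinations[longer$gene == "B"], 1L)
  expect_false("D" %in% longer$gene)
  expect_equal(inc$n_combinations[inc$gene == "E"], 1L)

  none <- inclusion_frequencies(res, q_threshold = 1e-6)
  expect_equal(nrow(none), 0)
})

test_that("MSI-stratified runs partition the cohort", {
  co <- make_null_cohort(seed = 47, n_samples = 150, n_genes = 100,
                         n_family = 8)
  cfg <- combo_config(n_background = 120, prevalence_threshold = 0.03,
                      seed = 2)
  mss <- co$clinical$sample[co$clinical$msi_status == "MSS"]
  msih <- co$clinical$sample[co$clinical$msi_status == "MSIH"]
  expect_length(intersect(mss, msih), 0)
  expect_setequal(c(mss, msih), co$clinical$sample)
  sc <- combo_scan(co$maf, co$clinical, co$expression, co$genes,
                   config = cfg, msi_status = "MSIH")
  expect_equal(sc$n_samples, length(msih))
})
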