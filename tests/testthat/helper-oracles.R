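# Independent brute-force oracles used to verify the package's statistics.
# Each is deliberately written as directly as possible, never sharing code
# with the implementation it checks.

# Product-limit estimate by explicit counting at each distinct event time.
oracle_km <- function(time, event) {
  ev <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev))
  s <- 1
  for (i in seq_along(ev)) {
    at_risk <- 0
    deaths <- 0
    for (j in seq_along(time)) {
      if (time[j] >= ev[i]) at_risk <- at_risk + 1
      if (time[j] == ev[i] && event[j] == 1) deaths <- deaths + 1
    }
    s <- s * (1 - deaths / at_risk)
    surv[i] <- s
  }
  data.frame(time = ev, survival = surv)
}

# Two-sided Fisher exact p by full enumeration of tables at fixed margins,
# using factorials directly.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  prob <- function(aa) {
    choose(r1, aa) * choose(r2, c1 - aa) / choose(r1 + r2, c1)
  }
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  p_obs <- prob(a)
  total <- 0
  for (aa in lo:hi) {
    pa <- prob(aa)
    if (pa <= p_obs * (1 + 1e-7)) total <- total + pa
  }
  min(1, total)
}

# Exact two-sided Mann-Whitney p by enumerating every split of the pooled
# midranks into the two groups.
oracle_mw_exact_p <- function(x, y) {
  m <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  mu <- m * n2 / 2
  u_obs <- sum(r[1:m]) - m * (m + 1) / 2
  splits <- utils::combn(m + n2, m)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Monte-Carlo permutation p for the Kruskal-Wallis H (tie-corrected),
# recomputing H from scratch per permutation with kruskal.test as engine.
oracle_kw_perm_p <- function(samples, B = 5000) {
  pooled <- unlist(samples)
  g <- rep(seq_along(samples), vapply(samples, length, integer(1)))
  h_of <- function(gg) unname(stats::kruskal.test(pooled, factor(gg))$statistic)
  h_obs <- h_of(g)
  hits <- 0
  for (b in seq_len(B)) {
    if (h_of(sample(g)) >= h_obs - 1e-12) hits <- hits + 1
  }
  hits / B
}

# Monte-Carlo permutation p for the two-group log-rank chi-square, using
# survival::survdiff as the independent statistic engine.
oracle_logrank_perm_p <- function(time, event, g, B = 5000) {
  chi_of <- function(gg) {
    survival::survdiff(survival::Surv(time, event) ~ gg)$chisq
  }
  chi_obs <- chi_of(g)
  hits <- 0
  for (b in seq_len(B)) {
    if (chi_of(sample(g)) >= chi_obs - 1e-12) hits <- hits + 1
  }
  hits / B
}

# Brute-force permutation p for the rank-ECDF sup-distance burden statistic
# (uniform, non-length-matched null), independent of the package loop.
oracle_ks_perm_p <- function(profiles, family, B) {
  ord <- order(-profiles$normalized_rate, profiles$gene)
  ranked <- profiles$gene[ord]
  n <- nrow(profiles)
  stat_of <- function(genes) {
    pos <- sort(which(ranked %in% genes))
    max(abs(seq_along(pos) / length(pos) - pos / n))
  }
  d_obs <- stat_of(family)
  m <- length(family)
  hits <- 0
  for (b in seq_len(B)) {
    if (stat_of(ranked[sample.int(n, m)]) >= d_obs - 1e-12) hits <- hits + 1
  }
  (1 + hits) / (B + 1)
}

is_proportion_val <- function(p) is.finite(p) && p >= 0 && p <= 1

# Small null cohort used across tests.
make_null_cohort <- function(seed = 1, n_samples = 120, n_genes = 200,
                             n_family = 15, ...) {
  simulate_cohort(sim_config(n_samples = n_samples, n_genes = n_genes,
                             n_family_genes = n_family, seed = seed, ...))
}

records_of <- function(cohort) famscan:::normalize_records(cohort$maf)

profiles_of <- function(cohort, classes = c("missense", "truncation", "other")) {
  gene_profiles(records_of(cohort), cohort$genes,
                family_genes = cohort$genes$gene[cohort$genes$in_family],
                classes = classes)
}

family_of <- function(cohort) cohort$genes$gene[cohort$genes$in_family]
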