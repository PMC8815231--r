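#' Rank-based comparison of alteration-frequency distributions
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test comparing the per-gene
#' alteration frequencies of the family against all other genes. Midranks
#' handle ties. For small samples (both groups of size at most 8, the exact
#' threshold) the null distribution of the U statistic is enumerated over
#' all group assignments, which remains valid under ties; otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param family_freqs Numeric vector of family-gene alteration frequencies.
#' @param other_freqs Numeric vector of background-gene frequencies.
#' @param method `"auto"` (exact when both groups <= 8), `"exact"`, or
#'   `"normal"`.
#' @return List of class `rank_test`: `statistic` (Mann-Whitney U for the
#'   family group), `p_value`, `n_family`, `n_background`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
rank_compare_frequencies <- function(family_freqs, other_freqs,
                                     method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(family_freqs) == 0L || length(other_freqs) == 0L) {
    stopf("both groups must be non-empty")
  }
  if (any(!is.finite(c(family_freqs, other_freqs)))) {
    stopf("frequencies must be finite")
  }
  m <- length(family_freqs)
  n2 <- length(other_freqs)
  pooled <- c(family_freqs, other_freqs)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n2 / 2

  use_exact <- switch(method,
                      exact = TRUE,
                      normal = FALSE,
                      auto = (m <= 8L && n2 <= 8L))
  if (use_exact && method == "exact" && (m > 10L || n2 > 10L)) {
    stopf("exact enumeration is limited to groups of size <= 10")
  }

  if (use_exact) {
    # enumerate all assignments of m pooled observations to the family group
    combos <- utils::combn(m + n2, m)
    rs <- colSums(matrix(r[combos], nrow = m))
    u_all <- rs - m * (m + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    used <- "exact"
  } else {
    N <- m + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- (m * n2 / 12) * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    used <- "normal_approx"
  }
  structure(list(statistic = u_obs, p_value = p, n_family = m,
                 n_background = n2, method = used),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): U = %.1f, p = %.3g (n = %d vs %d)\n",
              x$method, x$statistic, x$p_value, x$n_family, x$n_background))
  invisible(x)
}

# sup-distance between the ECDF of normalized family rank positions and the
# uniform reference, evaluated at the observed positions. A family occupying
# the top k of n genes scores 1 - k/n; a family equal to the whole gene list
# scores 0.
ks_rank_statistic <- function(positions, n_genes) {
  pos <- sort(positions)
  m <- length(pos)
  max(abs(seq_len(m) / m - pos / n_genes))
}

#' Moderated Kolmogorov-Smirnov gene-set mutation-burden test
#'
#' Tests whether a gene family is mutated above the cohort background while
#' accounting for gene size. Genes are ranked in decreasing order of their
#' length-normalized mutation rate (mutation events per coding base; ties
#' broken by gene symbol for determinism). The statistic is the sup-norm
#' distance between the empirical CDF of the family's normalized rank
#' positions and the uniform CDF. Significance comes from a permutation
#' null: random gene sets of the family's size, drawn either uniformly or
#' (default) from coding-length decile-matched bins so null sets resemble
#' the family in size *and* length. The p-value uses the add-one estimator
#' `(1 + #{null >= observed}) / (n_permutations + 1)`.
#'
#' @param profiles [gene_profiles()] output covering the whole exome.
#' @param family Character vector of family gene symbols (>= 2, all present
#'   in `profiles`).
#' @param n_permutations Number of null draws (>= 100).
#' @param length_matched Draw null sets from length-decile bins matching the
#'   family's length composition (default `TRUE`).
#' @param seed Integer seed for the permutation stream (`NULL` to use the
#'   current RNG state).
#' @return List of class `moderated_ks`: `ks_statistic`, `p_value`,
#'   `n_permutations`, `direction` (`"enriched"` or `"depleted"`), `seed`.
#' @export
moderated_ks_burden <- function(profiles, family, n_permutations = 1000L,
                                length_matched = TRUE, seed = NULL) {
  if (!all(c("gene", "normalized_rate", "coding_length") %in% names(profiles))) {
    stopf("profiles must be a gene_profiles() data frame")
  }
  missing <- setdiff(family, profiles$gene)
  if (length(missing) > 0L) {
    stopf("family gene(s) without a profile: %s",
          paste(missing, collapse = ", "))
  }
  if (length(family) < 2L) stopf("family must contain at least 2 genes")
  if (!is_count(n_permutations) || n_permutations < 100L) {
    stopf("n_permutations must be an integer >= 100")
  }
  n <- nrow(profiles)
  ord <- order(-profiles$normalized_rate, profiles$gene)
  ranked_genes <- profiles$gene[ord]
  rank_of <- stats::setNames(seq_len(n), ranked_genes)
  fam_pos <- sort(unname(rank_of[family]))
  m <- length(fam_pos)
  d_obs <- ks_rank_statistic(fam_pos, n)

  # length-matched bins: decile bins of coding length over all genes
  if (length_matched) {
    br <- unique(stats::quantile(profiles$coding_length,
                                 probs = seq(0, 1, length.out = 11)))
    if (length(br) < 2L) {
      bin <- rep(1L, n)
    } else {
      bin <- as.integer(cut(profiles$coding_length, breaks = br,
                            include.lowest = TRUE))
    }
    fam_bin <- bin[match(family, profiles$gene)]
    bin_counts <- table(factor(fam_bin, levels = sort(unique(bin))))
    bin_members <- split(rank_of[profiles$gene], bin)
  }

  local_seed(seed, {
    null_d <- numeric(n_permutations)
    null_meanpos <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      if (length_matched) {
        pos <- unlist(lapply(names(bin_counts), function(bn) {
          k <- bin_counts[[bn]]
          if (k == 0L) return(integer(0))
          mem <- bin_members[[bn]]
          mem[sample.int(length(mem), k)]
        }), use.names = FALSE)
      } else {
        pos <- sample.int(n, m)
      }
      null_d[b] <- ks_rank_statistic(pos, n)
      null_meanpos[b] <- mean(pos)
    }
    p <- (1 + sum(null_d >= d_obs - 1e-12)) / (n_permutations + 1)
    direction <- if (mean(fam_pos) < mean(null_meanpos)) "enriched" else "depleted"
    structure(list(ks_statistic = d_obs, p_value = p,
                   n_permutations = as.integer(n_permutations),
                   direction = direction, seed = seed),
              class = "moderated_ks")
  })
}

#' @export
print.moderated_ks <- function(x, ...) {
  cat(sprintf("Moderated KS burden test: D = %.3f, p = %.4g (%s, %d permutations)\n",
              x$ks_statistic, x$p_value, x$direction, x$n_permutations))
  invisible(x)
}
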