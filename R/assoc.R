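#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided p-value by summing the hypergeometric probabilities of all
#' tables (at the observed margins) no more probable than the observed one.
#' The odds ratio reported is the sample odds ratio, with the Haldane
#' 0.5-correction applied when any cell is zero.
#'
#' @param table 2x2 matrix of nonnegative integer counts (rows: mutation
#'   status strata; columns: clinical categories).
#' @return List with `p_value`, `odds_ratio`, and the input `table`.
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.matrix(table)
  if (!all(dim(x) == c(2L, 2L))) stopf("a 2x2 table is required")
  if (any(x < 0) || any(x != floor(x))) {
    stopf("cells must be nonnegative integers")
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    warnf("fisher_exact_2x2: empty margin; p = 1")
    return(list(p_value = 1, odds_ratio = NA_real_, table = x))
  }
  p <- stats::fisher.test(x)$p.value
  xc <- if (any(x == 0)) x + 0.5 else x
  or <- (xc[1, 1] * xc[2, 2]) / (xc[1, 2] * xc[2, 1])
  list(p_value = min(1, p), odds_ratio = or, table = x)
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Pearson statistic with `(r - 1)(c - 1)` degrees of freedom and an
#' upper-tail chi-square p-value (no continuity correction). A warning is
#' issued when any expected count falls below 5.
#'
#' @param table r x c matrix of nonnegative counts (r, c >= 2).
#' @return List with `statistic`, `p_value`, `df`, `expected`.
#' @export
chi_square_rxc <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 2L || ncol(x) < 2L) stopf("at least a 2x2 table is required")
  if (any(x < 0)) stopf("cells must be nonnegative")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stopf("chi_square_rxc: zero margin")
  }
  res <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  if (any(res$expected < 5)) {
    warnf("chi_square_rxc: %d expected count(s) below 5; the chi-square approximation may be poor",
          sum(res$expected < 5))
  }
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       df = unname(res$parameter), expected = res$expected)
}

# H statistic from pooled midranks and a group-label factor, with the
# standard tie correction. Used by both the exact-permutation path and the
# oracle-free fast path.
kw_statistic <- function(r, g, tie_factor, N) {
  sums <- rowsum(r, g)
  ns <- tabulate(g)
  h <- 12 / (N * (N + 1)) * sum(sums^2 / ns) - 3 * (N + 1)
  if (tie_factor > 0) h / tie_factor else 0
}

#' Kruskal-Wallis rank test
#'
#' Rank-based k-sample location test with midrank tie correction. The
#' default (`"auto"`) uses full enumeration of the permutation null when the
#' pooled sample size is at most 10, and the chi-square approximation with
#' `k - 1` degrees of freedom otherwise.
#'
#' @param samples List of at least two numeric vectors (e.g. protein
#'   positions per variant source), each non-empty.
#' @param method `"auto"`, `"approx"` (chi-square), or `"exact"`
#'   (permutation enumeration; pooled n must be <= 10).
#' @return List with `statistic` (tie-corrected H), `p_value`, `df`,
#'   `method`.
#' @export
kruskal_wallis <- function(samples, method = c("auto", "approx", "exact")) {
  method <- match.arg(method)
  if (!is.list(samples) || length(samples) < 2L) {
    stopf("samples must be a list of at least two groups")
  }
  if (any(vapply(samples, length, integer(1)) == 0L)) {
    stopf("every group must be non-empty")
  }
  pooled <- unlist(samples, use.names = FALSE)
  N <- length(pooled)
  k <- length(samples)
  g <- rep(seq_len(k), vapply(samples, length, integer(1)))
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = 0, p_value = 1, df = k - 1L,
                method = "degenerate"))
  }
  r <- rank(pooled)
  ties <- table(pooled)
  tie_factor <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h <- kw_statistic(r, g, tie_factor, N)

  use_exact <- switch(method, exact = TRUE, approx = FALSE, auto = N <= 10L)
  if (use_exact && N > 10L) {
    stopf("exact enumeration is limited to pooled n <= 10")
  }
  if (use_exact) {
    ns <- vapply(samples, length, integer(1))
    assignments <- enumerate_group_assignments(N, ns)
    h_all <- vapply(assignments, function(gg) {
      kw_statistic(r, gg, tie_factor, N)
    }, numeric(1))
    p <- mean(h_all >= h - 1e-12)
    used <- "exact"
  } else {
    if (N < 5L) {
      warnf("kruskal_wallis: pooled n below 5; the chi-square approximation is unreliable")
    }
    p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
    used <- "approx"
  }
  list(statistic = h, p_value = p, df = k - 1L, method = used)
}

# All distinct assignments of N pooled observations into groups of the
# given sizes, as group-label integer vectors. Multinomial enumeration via
# recursive combinations.
enumerate_group_assignments <- function(N, sizes) {
  recurse <- function(remaining, sizes_left, label) {
    if (length(sizes_left) == 1L) {
      g <- integer(0)
      out <- integer(N)
      out[remaining] <- label
      return(list(out))
    }
    k <- sizes_left[1]
    picks <- utils::combn(length(remaining), k, simplify = FALSE)
    res <- list()
    for (pk in picks) {
      chosen <- remaining[pk]
      rest <- remaining[-pk]
      tails <- recurse(rest, sizes_left[-1], label + 1L)
      for (tl in tails) {
        tl[chosen] <- label
        res[[length(res) + 1L]] <- tl
      }
    }
    res
  }
  recurse(seq_len(N), sizes, 1L)
}

#' Construct a protein-position sample
#'
#' Bundle of variant protein positions from one source (somatic calls or a
#' germline disease-variant database) on one gene.
#'
#' @param source `"somatic"` or `"germline"`.
#' @param gene Gene symbol.
#' @param positions Positive integer protein positions.
#' @param protein_length Optional protein length for range validation.
#' @return Object of class `position_sample`.
#' @export
position_sample <- function(source = c("somatic", "germline"), gene,
                            positions, protein_length = NULL) {
  source <- match.arg(source)
  if (length(positions) == 0L) stopf("positions must be non-empty")
  if (any(!is.finite(positions)) || any(positions < 1) ||
      any(positions != floor(positions))) {
    stopf("positions must be positive integers")
  }
  if (!is.null(protein_length) && any(positions > protein_length)) {
    stopf("positions exceed the protein length (%d)", protein_length)
  }
  structure(list(source = source, gene = gene,
                 positions = as.integer(positions),
                 protein_length = protein_length),
            class = "position_sample")
}

#' Compare somatic and germline variant position distributions
#'
#' Kruskal-Wallis comparison of the protein-position distributions of
#' somatic and germline variants on the same gene, with per-source binned
#' histograms and a table of recurrent positions (observed at least twice
#' in a source).
#'
#' @param somatic,germline [position_sample()] objects on the same gene.
#' @param bins Number of histogram bins across the protein.
#' @return List with `gene`, `p_value`, `statistic`, `histogram` (data
#'   frame: `bin_start`, `bin_end`, `somatic`, `germline`), `recurrent`
#'   (data frame: `source`, `position`, `count`), `medians`.
#' @export
compare_position_distributions <- function(somatic, germline, bins = 10L) {
  stopifnot(inherits(somatic, "position_sample"),
            inherits(germline, "position_sample"))
  if (!identical(somatic$gene, germline$gene)) {
    stopf("position samples are on different genes: %s vs %s",
          somatic$gene, germline$gene)
  }
  kw <- kruskal_wallis(list(somatic$positions, germline$positions),
                       method = "approx")
  L <- max(c(somatic$protein_length, germline$protein_length,
             somatic$positions, germline$positions))
  breaks <- unique(round(seq(0, L, length.out = bins + 1)))
  breaks[1] <- 0
  hs <- table(cut(somatic$positions, breaks = breaks))
  hg <- table(cut(germline$positions, breaks = breaks))
  histogram <- data.frame(
    bin_start = breaks[-length(breaks)] + 1,
    bin_end = breaks[-1],
    somatic = as.integer(hs),
    germline = as.integer(hg)
  )
  recur <- function(ps, src) {
    tb <- table(ps$positions)
    tb <- tb[tb >= 2]
    if (length(tb) == 0L) {
      return(data.frame(source = character(0), position = integer(0),
                        count = integer(0), stringsAsFactors = FALSE))
    }
    data.frame(source = src, position = as.integer(names(tb)),
               count = as.integer(tb), stringsAsFactors = FALSE)
  }
  recurrent <- rbind(recur(somatic, "somatic"), recur(germline, "germline"))
  recurrent <- recurrent[order(recurrent$source, -recurrent$count), ,
                         drop = FALSE]
  rownames(recurrent) <- NULL
  list(gene = somatic$gene,
       p_value = kw$p_value,
       statistic = kw$statistic,
       histogram = histogram,
       recurrent = recurrent,
       medians = c(somatic = stats::median(somatic$positions),
                   germline = stats::median(germline$positions)))
}

#' Association of mutation status with clinical categories
#'
#' Builds the mutation-status-by-category contingency table for each named
#' clinical variable and applies Fisher's exact test (2x2 tables) or the
#' Pearson chi-square test (larger tables) — the usual clinicopathological
#' association screen.
#'
#' @param status Logical or 0/1 vector: per-sample mutation status.
#' @param clinical Data frame of per-sample covariates, rows aligned with
#'   `status`.
#' @param variables Column names of `clinical` to test (categorical).
#' @return Data frame with `variable`, `test`, `statistic` (NA for Fisher),
#'   `p_value`.
#' @export
assoc_clinical <- function(status, clinical, variables) {
  status <- as.integer(as.logical(status))
  if (length(status) != nrow(clinical)) {
    stopf("status must align with clinical rows")
  }
  missing <- setdiff(variables, names(clinical))
  if (length(missing) > 0L) {
    stopf("clinical table lacks variable(s): %s",
          paste(missing, collapse = ", "))
  }
  rows <- lapply(variables, function(v) {
    tab <- table(status, clinical[[v]])
    if (all(dim(tab) == c(2L, 2L))) {
      res <- fisher_exact_2x2(tab)
      data.frame(variable = v, test = "fisher", statistic = NA_real_,
                 p_value = res$p_value, stringsAsFactors = FALSE)
    } else {
      res <- chi_square_rxc(tab)
      data.frame(variable = v, test = "chi_square",
                 statistic = res$statistic, p_value = res$p_value,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
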