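#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit estimator over the distinct event times of a
#' right-censored sample. Censored-only times reduce the at-risk counts but
#' do not appear as curve steps.
#'
#' @param records Data frame with columns `time` (months, >= 0) and `event`
#'   (1 = death observed, 0 = censored); a `sample` column is allowed and
#'   ignored.
#' @return Object of class `km_curve`: data frame with columns `time`
#'   (ascending distinct event times), `n_risk`, `n_event`, `survival`
#'   (nonincreasing, in (0, 1]).
#' @export
km_estimate <- function(records) {
  d <- validate_surv(records)
  if (all(d$time == 0) && all(d$event == 0)) {
    warnf("km_estimate: all times zero with no events; degenerate curve")
  }
  if (sum(d$event) == 0L) {
    warnf("km_estimate: no events observed; curve has no steps")
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0))
    return(structure(out, class = c("km_curve", "data.frame")))
  }
  et <- sort(unique(d$time[d$event == 1]))
  n_risk <- vapply(et, function(t) sum(d$time >= t), integer(1))
  n_event <- vapply(et, function(t) sum(d$time == t & d$event == 1), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                    survival = surv)
  structure(out, class = c("km_curve", "data.frame"))
}

#' Median survival from a Kaplan-Meier curve
#'
#' Smallest event time at which the survival estimate drops to 0.5 or
#' below; `NA` if the curve never reaches 0.5.
#'
#' @param curve A [km_estimate()] result.
#' @return Numeric scalar (months) or `NA`.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$survival <= 0.5 + 1e-12)
  if (length(hit) == 0L) NA_real_ else curve$time[hit[1]]
}

# Precompute the risk-set structure of a cohort once so that many two-group
# log-rank tests against the same survival data are cheap. Groups of tied
# times are collapsed; only groups containing events contribute.
logrank_prep <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]
  e_s <- as.numeric(event[ord])
  new_grp <- c(TRUE, t_s[-1] != t_s[-n])
  start <- which(new_grp)
  end <- c(start[-1] - 1L, n)
  gid <- cumsum(new_grp)
  d <- as.vector(rowsum(e_s, gid))
  keep <- d > 0
  list(ord = ord, n = n, e_s = e_s,
       start = start[keep], end = end[keep], d = d[keep],
       n_risk = n - start[keep] + 1L)
}

# Unweighted two-group log-rank from a prep and a 0/1 group indicator
# (aligned with the original, pre-sort order). Returns observed/expected
# event totals for group 1 and the chi-square.
logrank_engine <- function(prep, x) {
  xs <- as.numeric(x)[prep$ord]
  r1 <- rev(cumsum(rev(xs)))
  n1 <- r1[prep$start]
  ce <- c(0, cumsum(xs * prep$e_s))
  d1 <- ce[prep$end + 1L] - ce[prep$start]
  nr <- prep$n_risk
  d <- prep$d
  e1 <- d * n1 / nr
  v <- ifelse(nr > 1, d * (n1 / nr) * (1 - n1 / nr) * (nr - d) / (nr - 1), 0)
  o1 <- sum(d1)
  E1 <- sum(e1)
  V <- sum(v)
  if (V <= 0) {
    list(chi_square = 0, p_value = 1, o1 = o1, e1 = E1, v = V,
         o2 = sum(d) - o1, e2 = sum(d) - E1, zero_var = TRUE)
  } else {
    chi <- (o1 - E1)^2 / V
    list(chi_square = chi, p_value = stats::pchisq(chi, 1, lower.tail = FALSE),
         o1 = o1, e1 = E1, v = V, o2 = sum(d) - o1, e2 = sum(d) - E1,
         zero_var = FALSE)
  }
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of two right-censored groups:
#' at each distinct event time the expected events per group come from the
#' hypergeometric mean, the variance from the hypergeometric variance, and
#' the statistic is `(O - E)^2 / V`, referred to a chi-square with 1 df.
#'
#' @param group_a,group_b Data frames of survival records (columns `time`,
#'   `event`).
#' @return Object of class `logrank`: `chi_square`, `p_value`,
#'   `observed_events` (group a, group b), `expected_events`.
#' @export
logrank_test <- function(group_a, group_b) {
  a <- validate_surv(group_a)
  b <- validate_surv(group_b)
  if (sum(a$event) + sum(b$event) == 0L) {
    stopf("log-rank test requires at least one event")
  }
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  x <- c(rep(1, nrow(a)), rep(0, nrow(b)))
  prep <- logrank_prep(time, event)
  res <- logrank_engine(prep, x)
  if (res$zero_var) {
    warnf("logrank_test: zero variance (no comparable risk sets); p = 1")
  }
  structure(list(chi_square = res$chi_square, p_value = res$p_value,
                 observed_events = c(a = res$o1, b = res$o2),
                 expected_events = c(a = res$e1, b = res$e2)),
            class = "logrank")
}

#' @export
print.logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  cat(sprintf("  observed events: %g vs %g; expected: %.2f vs %.2f\n",
              x$observed_events[1], x$observed_events[2],
              x$expected_events[1], x$expected_events[2]))
  invisible(x)
}

# Partial log-likelihood, gradient and information of the Cox model at a
# given coefficient vector, with Efron or Breslow tie handling. X rows must
# be sorted by *descending* time with tie groups contiguous; `groups` lists
# row index ranges per distinct time, `death_idx` rows with events.
cox_loglik <- function(beta, X, groups, ties) {
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  S0 <- 0
  S1 <- numeric(p)
  S2 <- matrix(0, p, p)
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (g in groups) {
    idx <- g$rows
    Xg <- X[idx, , drop = FALSE]
    wg <- w[idx]
    S0 <- S0 + sum(wg)
    S1 <- S1 + colSums(Xg * wg)
    S2 <- S2 + crossprod(Xg, Xg * wg)
    di <- g$deaths
    d <- length(di)
    if (d == 0L) next
    Xd <- X[di, , drop = FALSE]
    wd <- w[di]
    ll <- ll + sum(eta[di])
    if (ties == "breslow" || d == 1L) {
      ll <- ll - d * log(S0)
      grad <- grad + colSums(Xd) - d * S1 / S0
      info <- info + d * (S2 / S0 - tcrossprod(S1 / S0))
    } else {
      a0 <- sum(wd)
      a1 <- colSums(Xd * wd)
      a2 <- crossprod(Xd, Xd * wd)
      grad <- grad + colSums(Xd)
      for (l in 0:(d - 1)) {
        f <- l / d
        phi <- S0 - f * a0
        z1 <- S1 - f * a1
        z2 <- S2 - f * a2
        ll <- ll - log(phi)
        grad <- grad - z1 / phi
        info <- info + z2 / phi - tcrossprod(z1 / phi)
      }
    }
  }
  list(ll = ll, grad = grad, info = info)
}

#' Cox proportional-hazards fit by Newton-Raphson
#'
#' Maximizes the Cox partial likelihood with Efron (default) or Breslow tie
#' handling. Convergence is declared when the gradient max-norm falls below
#' `tol`; step-halving guards against likelihood decreases. The score test
#' at the null (all coefficients zero) is returned as well — for a single
#' binary covariate without tied event times it equals the log-rank
#' chi-square.
#'
#' @param records Data frame with `time` and `event` columns.
#' @param covariates Numeric matrix or data frame (one row per record):
#'   binary indicators or continuous covariates; no constant columns.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `cox_fit`: named `coefficients` (log hazard
#'   ratios), `hazard_ratios`, `standard_errors`, `z`, `wald_p_values`,
#'   `ci_lower`/`ci_upper` (95%, hazard-ratio scale), `n_iterations`,
#'   `converged`, `log_partial_likelihood`, `score_chisq` (at beta = 0,
#'   with df = number of covariates), `n`, `n_events`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  d <- validate_surv(records)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (nrow(X) != nrow(d)) {
    stopf("covariates must have one row per survival record")
  }
  if (any(!is.finite(X))) stopf("covariates must be finite numeric")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  constant <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(constant)) {
    stopf("constant covariate column(s): %s",
          paste(colnames(X)[constant], collapse = ", "))
  }
  if (sum(d$event) == 0L) stopf("Cox fit requires at least one event")

  ord <- order(-d$time, d$event)
  Xs <- X[ord, , drop = FALSE]
  ts <- d$time[ord]
  es <- d$event[ord]
  n <- length(ts)
  new_grp <- c(TRUE, ts[-1] != ts[-n])
  start <- which(new_grp)
  end <- c(start[-1] - 1L, n)
  groups <- lapply(seq_along(start), function(i) {
    rows <- start[i]:end[i]
    list(rows = rows, deaths = rows[es[rows] == 1])
  })

  p <- ncol(X)
  beta <- numeric(p)
  state <- cox_loglik(beta, Xs, groups, ties)
  score_chisq <- tryCatch(
    drop(t(state$grad) %*% solve(state$info, state$grad)),
    error = function(e) stopf("singular information matrix at beta = 0")
  )
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(state$grad)) < tol) {
      converged <- TRUE
      break
    }
    delta <- tryCatch(solve(state$info, state$grad),
                      error = function(e) stopf("singular information matrix"))
    step <- 1
    repeat {
      cand <- beta + step * delta
      cand_state <- cox_loglik(cand, Xs, groups, ties)
      if (is.finite(cand_state$ll) && cand_state$ll >= state$ll - 1e-12) break
      step <- step / 2
      if (step < 2^-20) break
    }
    beta <- beta + step * delta
    state <- cand_state
  }
  if (!converged && max(abs(state$grad)) < tol) converged <- TRUE
  if (!converged || any(abs(beta) > 15)) {
    if (any(abs(beta) > 15)) {
      warnf("cox_fit: possible monotone likelihood (complete separation); coefficients unreliable")
      converged <- FALSE
    } else {
      warnf("cox_fit: Newton-Raphson did not converge in %d iterations", max_iter)
    }
  }
  vcov <- tryCatch(solve(state$info),
                   error = function(e) stopf("singular information matrix"))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  wald_p <- 2 * stats::pnorm(-abs(z))
  crit <- stats::qnorm(0.975)
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    hazard_ratios = stats::setNames(exp(beta), colnames(X)),
    standard_errors = stats::setNames(se, colnames(X)),
    z = stats::setNames(z, colnames(X)),
    wald_p_values = stats::setNames(wald_p, colnames(X)),
    ci_lower = stats::setNames(exp(beta - crit * se), colnames(X)),
    ci_upper = stats::setNames(exp(beta + crit * se), colnames(X)),
    n_iterations = iter, converged = converged,
    log_partial_likelihood = state$ll,
    score_chisq = score_chisq, score_df = p,
    n = n, n_events = sum(es)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (n = %d, events = %d, %sconverged)\n",
              x$n, x$n_events, if (x$converged) "" else "NOT "))
  tab <- data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                    se = x$standard_errors,
                    `lower95` = x$ci_lower, `upper95` = x$ci_upper,
                    p = x$wald_p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Univariate screening followed by multivariate Cox fit
#'
#' Fits each covariate alone, carries forward those with Wald p below
#' `p_threshold`, and fits the retained covariates jointly — the common
#' clinical-report workflow of selecting multivariate covariates by
#' univariate significance.
#'
#' @param records Data frame with `time` and `event` columns.
#' @param covariates Numeric matrix or data frame.
#' @param p_threshold Univariate Wald p-value cutoff (default 0.05).
#' @param ... Passed to [cox_fit()].
#' @return List with `univariate` (data frame of per-covariate HR, CI, p),
#'   `selected` (covariate names carried forward) and `multivariate`
#'   (a [cox_fit()] or `NULL` when fewer than one covariate is selected).
#' @export
cox_univariate_screen <- function(records, covariates, p_threshold = 0.05,
                                  ...) {
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  uni <- lapply(colnames(X), function(v) {
    fit <- cox_fit(records, X[, v, drop = FALSE], ...)
    data.frame(covariate = v, coef = fit$coefficients[[1]],
               hazard_ratio = fit$hazard_ratios[[1]],
               ci_lower = fit$ci_lower[[1]], ci_upper = fit$ci_upper[[1]],
               p_value = fit$wald_p_values[[1]], stringsAsFactors = FALSE)
  })
  uni <- do.call(rbind, uni)
  selected <- uni$covariate[uni$p_value < p_threshold]
  multi <- if (length(selected) >= 1L) {
    cox_fit(records, X[, selected, drop = FALSE], ...)
  } else {
    NULL
  }
  list(univariate = uni, selected = selected, multivariate = multi)
}
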