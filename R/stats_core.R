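#' @title Core statistical procedures
#' @description Self-contained, formula-level implementations of the
#'   statistical procedures the pipeline relies on: Pearson correlation with a
#'   t-distribution p-value, unpaired two-tailed t-tests (pooled or Welch),
#'   Holm-Sidak and Benjamini-Hochberg multiplicity adjustment, the
#'   Kaplan-Meier product-limit estimator, the two-group log-rank (Mantel-Cox)
#'   test, and univariate Cox regression with Breslow tie handling.  Each is
#'   implemented directly from its defining formula so that equivalence with
#'   independent oracles is testable; reference libraries are used only as
#'   cross-checks in the test suite.
#' @name stats_core
NULL

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation of two numeric vectors, with the two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` referred to a
#' t-distribution on `n - 2` degrees of freedom.  `|r| = 1` (within 1e-12)
#' returns `p = 0`.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with positive
#'   variance.  Pairs with a missing value in either vector are dropped.
#' @return list with `r`, `p_value`, `n`, `df`, `statistic` (the t value).
#' @export
pearson_r_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("pearson_r_p: need at least 3 complete pairs")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("pearson_r_p: zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1 - 1e-12) {
    return(list(r = sign(r), p_value = 0, n = n, df = n - 2, statistic = Inf * sign(r)))
  }
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(r = r, p_value = p, n = n, df = n - 2, statistic = tval)
}

#' Unpaired two-tailed t-test
#'
#' Student (pooled-variance) test by default, mirroring a plain "unpaired
#' t-test"; Welch's unequal-variance form is available.  When both groups have
#' zero variance and equal means the result is the degenerate convention
#' `t = 0, p = 1` with `degenerate = TRUE`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variance_mode `"pooled"` (default) or `"welch"`.
#' @return list with `statistic`, `df`, `p_value`, `effect` (mean(a) - mean(b)),
#'   `degenerate`.
#' @export
ttest_unpaired <- function(a, b, variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("ttest_unpaired: each group needs n >= 2")
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  degenerate <- FALSE
  if (v1 == 0 && v2 == 0) {
    degenerate <- TRUE
    if (m1 == m2) {
      return(list(statistic = 0, df = n1 + n2 - 2, p_value = 1,
                  effect = 0, degenerate = TRUE))
    }
    return(list(statistic = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p_value = 0,
                effect = m1 - m2, degenerate = TRUE))
  }
  if (variance_mode == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tval <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tval), df = df)
  list(statistic = tval, df = df, p_value = p, effect = m1 - m2,
       degenerate = degenerate)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts p-values ascending, sets `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`,
#' enforces monotone non-decrease along the sorted order, caps at 1, and
#' returns adjusted values in the original order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
holm_sidak <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("holm_sidak: p-values must be finite and in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Benjamini-Hochberg q-values (step-up FDR)
#'
#' `q_(i) = min over j >= i of p_(j) * m / j` along the ascending-sorted
#' order, capped at 1, returned in the original order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("bh_fdr: p-values must be finite and in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  q <- rev(cummin(rev(ps * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survival step function S(t) from right-censored data, with
#' S(0) = 1.  The median is the smallest event time with S(t) <= 0.5, reported
#' `NA` ("not reached") when the curve never drops to 0.5.
#'
#' @param time positive event/censoring times.
#' @param event 1 = event observed, 0 = right-censored.
#' @return object of class `km_curve`: data.frame component `table` with
#'   columns (time, n_risk, n_event, n_censor, surv) over distinct observed
#'   times, plus `median` and `n`.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) stop("km_curve: need at least one record")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("km_curve: times must be finite and positive")
  }
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("km_curve: event must be 0 or 1")
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1L), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0L), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  tab <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv)
  below <- tab$time[tab$n_event > 0 & tab$surv <= 0.5 + 1e-12]
  med <- if (length(below)) min(below) else NA_real_
  structure(list(table = tab, median = med, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, sum(x$table$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Observed-minus-expected events over shared risk sets at each distinct event
#' time; chi-squared statistic on 1 degree of freedom.  With zero events the
#' degenerate result `chisq = 0, p = 1` is returned with a warning.
#'
#' @param time positive times.
#' @param event 1 = event, 0 = censored.
#' @param group group labels; exactly two distinct values required.
#' @return list with `statistic` (chi-squared), `df = 1`, `p_value`,
#'   `observed` and `expected` events per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  levs <- sort(unique(group))
  if (length(levs) != 2) stop("logrank_test: exactly two groups required")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("logrank_test: times must be finite and positive")
  }
  event <- as.integer(event)
  if (sum(event) == 0) {
    warning("logrank_test: no events in either group; p = 1")
    return(list(statistic = 0, df = 1, p_value = 1,
                observed = c(0, 0), expected = c(0, 0), groups = levs))
  }
  g1 <- group == levs[1]
  etimes <- sort(unique(time[event == 1L]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in etimes) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & g1)
    dj <- sum(time == t & event == 1L)
    d1j <- sum(time == t & event == 1L & g1)
    O1 <- O1 + d1j
    E1 <- E1 + dj * n1j / nj
    if (nj > 1) {
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
  }
  Otot <- sum(event)
  if (V <= 0) {
    warning("logrank_test: zero variance of the log-rank statistic; p = 1")
    return(list(statistic = 0, df = 1, p_value = 1,
                observed = c(O1, Otot - O1), expected = c(E1, Otot - E1),
                groups = levs))
  }
  chisq <- (O1 - E1)^2 / V
  list(statistic = chisq, df = 1,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = c(O1, Otot - O1), expected = c(E1, Otot - E1),
       groups = levs)
}

#' Univariate Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the Breslow partial likelihood for a single
#' binary (or numeric) covariate.  Returns the hazard ratio `exp(beta)` with a
#' Wald 95% confidence interval from the observed information.  Convergence
#' tolerance 1e-8 on the Newton step, at most 50 iterations; a monotone
#' partial likelihood (complete separation of event orderings) raises a
#' non-convergence error.
#'
#' @param time positive times.
#' @param event 1 = event, 0 = censored.
#' @param x covariate; a two-level factor/character is coded 0/1 in sorted
#'   level order (second level = 1).
#' @return list with `beta`, `hr`, `se`, `ci_low`, `ci_high`, `p_value`
#'   (Wald), `iterations`, `loglik`.
#' @export
cox_univariate <- function(time, event, x) {
  if (is.character(x) || is.factor(x)) {
    levs <- sort(unique(as.character(x)))
    if (length(levs) != 2) stop("cox_univariate: covariate must have 2 levels")
    x <- as.numeric(as.character(x) == levs[2])
  }
  x <- as.numeric(x)
  event <- as.integer(event)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("cox_univariate: times must be finite and positive")
  }
  if (sum(event) < 2) stop("cox_univariate: need at least 2 events")
  if (length(unique(x)) < 2) stop("cox_univariate: covariate is constant")

  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  etimes <- unique(time[event == 1L])

  loglik_score_info <- function(beta) {
    ll <- 0; score <- 0; info <- 0
    ex <- exp(beta * x)
    for (t in etimes) {
      rs <- time >= t
      s0 <- sum(ex[rs])
      s1 <- sum(ex[rs] * x[rs])
      s2 <- sum(ex[rs] * x[rs]^2)
      dd <- time == t & event == 1L
      dj <- sum(dd)
      ll <- ll + beta * sum(x[dd]) - dj * log(s0)
      score <- score + sum(x[dd]) - dj * s1 / s0
      info <- info + dj * (s2 / s0 - (s1 / s0)^2)
    }
    list(ll = ll, score = score, info = info)
  }

  beta <- 0
  iter <- 0
  repeat {
    iter <- iter + 1
    d <- loglik_score_info(beta)
    if (d$info <= 0) stop("cox_univariate: singular information matrix")
    step <- d$score / d$info
    beta <- beta + step
    if (abs(beta) > 15) {
      stop("cox_univariate: monotone partial likelihood (complete separation); no finite estimate")
    }
    if (abs(step) < 1e-8) break
    if (iter >= 50) stop("cox_univariate: Newton iteration failed to converge in 50 steps")
  }
  d <- loglik_score_info(beta)
  se <- 1 / sqrt(d$info)
  z <- beta / se
  zq <- stats::qnorm(0.975)
  list(beta = beta, hr = exp(beta), se = se,
       ci_low = exp(beta - zq * se), ci_high = exp(beta + zq * se),
       p_value = 2 * stats::pnorm(-abs(z)),
       iterations = iter, loglik = d$ll)
}
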