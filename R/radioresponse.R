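#' @title Radiosensitivity quantification
#' @description Surviving fractions from clonogenic assays, constrained
#'   linear-quadratic fits, the mean inactivating dose Dmid (area under the
#'   linear-scale survival curve), enhancement ratios, and GI50-based
#'   enhancement from viability dose-response data.
#' @name radioresponse
NULL

#' Surviving fractions from clonogenic colony counts
#'
#' Plating efficiency PE = mean over dose-0 replicates of colonies/cells
#' plated; SF(d) = mean over replicates of colonies/cells plated at dose d,
#' divided by PE.  SF(0) = 1 by construction.  Doses at which every replicate
#' yields zero colonies are reported with SF = 0 and flagged (a log-scale fit
#' cannot use them).
#'
#' @param assay clonogenic data.frame (cell_line, treatment, dose_gy,
#'   cells_plated, colonies, replicate) or at minimum (dose_gy, cells_plated,
#'   colonies).
#' @return data.frame (dose_gy, sf, se, n) with attribute `pe`; `se` is the
#'   replicate standard error of SF.
#' @export
surviving_fractions <- function(assay) {
  req <- c("dose_gy", "cells_plated", "colonies")
  if (!all(req %in% names(assay))) {
    stop(sprintf("surviving_fractions: need columns %s", paste(req, collapse = ", ")))
  }
  if (any(assay$colonies > assay$cells_plated)) {
    stop("validation error: colonies exceed cells plated")
  }
  if (any(assay$colonies < 0) || any(assay$cells_plated <= 0)) {
    stop("validation error: counts must be non-negative and cells_plated > 0")
  }
  if (!any(assay$dose_gy == 0)) stop("assay error: dose-0 records required")
  frac <- assay$colonies / assay$cells_plated
  pe <- mean(frac[assay$dose_gy == 0])
  if (pe <= 0) stop("assay error: plating efficiency is zero")
  doses <- sort(unique(assay$dose_gy))
  res <- lapply(doses, function(d) {
    f <- frac[assay$dose_gy == d]
    sfv <- mean(f) / pe
    se <- if (length(f) > 1) stats::sd(f) / sqrt(length(f)) / pe else NA_real_
    data.frame(dose_gy = d, sf = sfv, se = se, n = length(f))
  })
  out <- do.call(rbind, res)
  if (any(out$sf == 0 & out$dose_gy > 0)) {
    warning("surviving_fractions: zero colonies in all replicates at some dose(s); SF = 0 flagged")
  }
  attr(out, "pe") <- pe
  out
}

#' Constrained linear-quadratic fit
#'
#' Least-squares fit of `ln SF = -(alpha*d + beta*d^2)` with `alpha >= 0` and
#' `beta >= 0`.  The two-parameter non-negative least-squares problem is
#' solved exactly: the unconstrained normal-equations solution is used when
#' feasible, otherwise the best of the boundary fits (alpha = 0, beta = 0,
#' or both) by residual sum of squares.  Surviving fractions must be positive
#' and finite; values slightly above 1 (measurement noise at low dose) are
#' accepted since the log remains defined.
#'
#' @param doses dose values (Gy), at least 3 distinct positive doses.
#' @param sf surviving fractions, same length, all > 0.
#' @param weights optional non-negative weights on the log scale (e.g. inverse
#'   replicate variances); default unweighted.
#' @return list with `alpha` (1/Gy), `beta` (1/Gy^2), `rss` (residual sum of
#'   squares on the log scale), `n`.
#' @export
fit_lq <- function(doses, sf, weights = NULL) {
  if (length(doses) != length(sf)) stop("fit_lq: doses and sf lengths differ")
  keep <- is.finite(doses) & is.finite(sf)
  doses <- doses[keep]; sf <- sf[keep]
  if (is.null(weights)) weights <- rep(1, length(doses)) else weights <- weights[keep]
  if (any(sf <= 0)) stop("validation error: surviving fractions must be > 0 (drop zero-SF doses)")
  pos <- doses > 0
  if (length(unique(doses[pos])) < 3) {
    stop("underdetermined-fit error: need at least 3 distinct positive doses")
  }
  d <- doses[pos]; y <- -log(sf[pos]); w <- weights[pos]
  X <- cbind(d, d^2)
  rss_of <- function(ab) sum(w * (y - X %*% ab)^2)
  cand <- list()
  fit_ls <- function(Xm) {
    A <- crossprod(Xm * sqrt(w))
    b <- crossprod(Xm * w, y)
    drop(solve(A, b))
  }
  full <- tryCatch(fit_ls(X), error = function(e) NULL)
  if (!is.null(full) && all(full >= 0)) {
    cand[[length(cand) + 1L]] <- full
  }
  a_only <- max(0, sum(w * d * y) / sum(w * d^2))
  cand[[length(cand) + 1L]] <- c(a_only, 0)
  b_only <- max(0, sum(w * d^2 * y) / sum(w * d^4))
  cand[[length(cand) + 1L]] <- c(0, b_only)
  cand[[length(cand) + 1L]] <- c(0, 0)
  rss <- vapply(cand, rss_of, numeric(1))
  best <- cand[[which.min(rss)]]
  list(alpha = unname(best[1]), beta = unname(best[2]),
       rss = min(rss), n = length(d))
}

#' Mean inactivating dose (Dmid)
#'
#' Dmid is the area under the clonogenic survival curve on a linear SF axis.
#' `method = "fitted"` integrates `exp(-(alpha*d + beta*d^2))` over
#' `[0, dose_max]` by adaptive quadrature (absolute tolerance 1e-8);
#' `method = "trapezoid"` integrates the measured surviving fractions over the
#' assayed dose range by the trapezoidal rule (model-free).
#'
#' @param alpha,beta linear-quadratic parameters (fitted method).
#' @param dose_max upper integration limit (Gy), > 0.
#' @param method `"fitted"` or `"trapezoid"`.
#' @param doses,sf measured curve including dose 0 (trapezoid method).
#' @return Dmid in Gy.
#' @export
dmid <- function(alpha = NULL, beta = NULL, dose_max,
                 method = c("fitted", "trapezoid"),
                 doses = NULL, sf = NULL) {
  method <- match.arg(method)
  if (!(dose_max > 0)) stop("dmid: dose_max must be > 0")
  if (method == "fitted") {
    if (is.null(alpha) || is.null(beta)) stop("dmid: fitted method needs alpha and beta")
    if (alpha < 0 || beta < 0) stop("dmid: alpha and beta must be >= 0")
    f <- function(d) exp(-(alpha * d + beta * d^2))
    res <- stats::integrate(f, 0, dose_max, abs.tol = 1e-8, rel.tol = 1e-10,
                            subdivisions = 500L)
    return(res$value)
  }
  if (is.null(doses) || is.null(sf)) stop("dmid: trapezoid method needs doses and sf")
  o <- order(doses)
  doses <- doses[o]; sf <- sf[o]
  if (doses[1] != 0) stop("dmid: trapezoid method requires a dose-0 measurement")
  if (dose_max < max(doses)) {
    stop("range error: dose_max below the largest assayed dose")
  }
  sum(diff(doses) * (utils::head(sf, -1) + utils::tail(sf, -1)) / 2)
}

#' Radiosensitization enhancement ratio
#'
#' ER = Dmid(control) / Dmid(treatment) (or the analogous GI50 ratio).
#' ER > 1 indicates radiosensitization, ER < 1 radioprotection; equality
#' within 1e-6 is classified neutral.
#'
#' @param dmid_control,dmid_treatment Dmid (or GI50) values in Gy, both > 0,
#'   computed over the same dose range.
#' @param basis `"dmid"` or `"gi50"` (provenance label).
#' @return list with `er`, `dmid_control`, `dmid_treatment`, `basis`,
#'   `classification`.
#' @export
enhancement_ratio <- function(dmid_control, dmid_treatment,
                              basis = c("dmid", "gi50")) {
  basis <- match.arg(basis)
  if (!(dmid_control > 0) || !(dmid_treatment > 0)) {
    stop("domain error: Dmid values must be > 0")
  }
  er <- dmid_control / dmid_treatment
  classification <- if (abs(er - 1) <= 1e-6) "neutral"
    else if (er > 1) "radiosensitization" else "radioprotection"
  list(er = er, dmid_control = dmid_control, dmid_treatment = dmid_treatment,
       basis = basis, classification = classification)
}

#' GI50 from a viability dose-response
#'
#' The dose at which viability first crosses 50% of the unirradiated (dose-0)
#' value, by linear interpolation between the bracketing measured doses.  No
#' extrapolation: if viability never reaches 50% within the assayed range, a
#' not-reached error is raised.
#'
#' @param doses dose values (Gy) including 0.
#' @param viability viability at each dose, same units throughout (percent or
#'   fraction of untreated); all values > 0.
#' @return GI50 in Gy.
#' @export
gi50 <- function(doses, viability) {
  if (length(doses) != length(viability)) stop("gi50: lengths differ")
  if (length(doses) < 2) stop("gi50: need at least 2 doses")
  if (any(viability <= 0)) stop("gi50: viability values must be positive")
  o <- order(doses)
  doses <- doses[o]; viability <- viability[o]
  if (doses[1] != 0) stop("gi50: dose-0 (unirradiated) measurement required")
  target <- viability[1] / 2
  for (i in seq_along(doses)) {
    if (viability[i] <= target) {
      if (viability[i] == target || i == 1) return(doses[i])
      d0 <- doses[i - 1]; d1 <- doses[i]
      v0 <- viability[i - 1]; v1 <- viability[i]
      return(d0 + (d1 - d0) * (v0 - target) / (v0 - v1))
    }
  }
  stop("not-reached error: viability never crosses 50% within the assayed dose range")
}

#' Fit a full survival curve from a clonogenic assay
#'
#' Convenience wrapper: surviving fractions, constrained linear-quadratic fit
#' (zero-SF doses dropped from the fit with a warning), and Dmid by both the
#' fitted and trapezoid methods.  By default the log-scale fit is weighted by
#' the total colony count observed at each dose — the inverse-variance weight
#' for log-transformed Poisson counts, which stops the near-empty high-dose
#' plates from dominating the fit (`weighting = "none"` gives the unweighted
#' fit).
#'
#' @param assay clonogenic data.frame for a single (cell_line, treatment).
#' @param dose_max Dmid integration limit; default the maximum assayed dose.
#' @param weighting `"colonies"` (default) or `"none"`.
#' @return list of class `survival_curve`: `curve` (dose_gy, sf, se, n),
#'   `alpha`, `beta`, `rss`, `dmid_fitted`, `dmid_trapezoid`, `pe`,
#'   `dose_max`.
#' @export
fit_survival_curve <- function(assay, dose_max = NULL,
                               weighting = c("colonies", "none")) {
  weighting <- match.arg(weighting)
  sfs <- surviving_fractions(assay)
  if (is.null(dose_max)) dose_max <- max(sfs$dose_gy)
  usable <- sfs$sf > 0
  w <- if (weighting == "colonies") {
    tot <- tapply(assay$colonies, assay$dose_gy, sum)
    as.numeric(tot[as.character(sfs$dose_gy)])[usable]
  } else NULL
  fit <- fit_lq(sfs$dose_gy[usable], sfs$sf[usable], weights = w)
  structure(list(curve = sfs, alpha = fit$alpha, beta = fit$beta,
                 rss = fit$rss,
                 dmid_fitted = dmid(fit$alpha, fit$beta, dose_max, "fitted"),
                 dmid_trapezoid = dmid(dose_max = max(sfs$dose_gy),
                                       method = "trapezoid",
                                       doses = sfs$dose_gy, sf = sfs$sf),
                 pe = attr(sfs, "pe"), dose_max = dose_max),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("LQ survival curve: alpha = %.4g /Gy, beta = %.4g /Gy^2, Dmid(fitted) = %.4g Gy, Dmid(trapezoid) = %.4g Gy\n",
              x$alpha, x$beta, x$dmid_fitted, x$dmid_trapezoid))
  invisible(x)
}
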