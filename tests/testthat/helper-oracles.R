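# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different code paths: naive loops, base-R scale(),
# cor.test(), p.adjust(), grid search over the partial likelihood.

# naive per-row standardization; returns list(z, dropped)
oracle_z <- function(mat) {
  z <- mat
  dropped <- character(0)
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0 || sum(!is.na(v)) < 2) {
      dropped <- c(dropped, rownames(mat)[i])
      z[i, ] <- NA_real_
      next
    }
    z[i, ] <- (v - mean(v, na.rm = TRUE)) / s
  }
  list(z = z[!(rownames(mat) %in% dropped), , drop = FALSE], dropped = dropped)
}

oracle_calls <- function(z, lo = -1, hi = 1) {
  out <- matrix(NA_integer_, nrow(z), ncol(z), dimnames = dimnames(z))
  for (i in seq_len(nrow(z))) for (j in seq_len(ncol(z))) {
    v <- z[i, j]
    if (is.na(v)) next
    out[i, j] <- if (v < lo) -1L else if (v > hi) 1L else 0L
  }
  out
}

oracle_scores <- function(calls, map) {
  rows <- list()
  for (pw in unique(map$pathway)) {
    mets <- intersect(map$metabolite[map$pathway == pw], rownames(calls))
    if (!length(mets)) next
    for (cl in colnames(calls)) {
      v <- calls[mets, cl]
      n <- sum(!is.na(v))
      if (n == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = pw, cell_line = cl, down_score = NA_real_,
          up_score = NA_real_, n_measured = 0L, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          pathway = pw, cell_line = cl,
          down_score = sum(v == -1L, na.rm = TRUE) / n,
          up_score = sum(v == 1L, na.rm = TRUE) / n,
          n_measured = n, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# cor.test + p.adjust based correlation family, mirroring the documented
# conventions: sensitivity orientation (-dmid), zero-variance vectors skipped,
# BH across the tested pathways of one direction.
oracle_correlations <- function(scores, resistance, direction) {
  scol <- if (direction == "down") "down_score" else "up_score"
  lines <- intersect(unique(scores$cell_line), resistance$cell_line)
  target <- -resistance$dmid[match(lines, resistance$cell_line)]
  pws <- unique(scores$pathway)
  r <- p <- rep(NA_real_, length(pws))
  for (k in seq_along(pws)) {
    sub <- scores[scores$pathway == pws[k], ]
    v <- sub[[scol]][match(lines, sub$cell_line)]
    ok <- is.finite(v)
    if (sum(ok) < 3 || stats::sd(v[ok]) == 0) next
    ct <- stats::cor.test(v[ok], target[ok])
    r[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
  }
  q <- rep(NA_real_, length(pws))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  data.frame(pathway = pws, r = r, p = p, q = q, stringsAsFactors = FALSE)
}

# Breslow partial log-likelihood, naive double loop
oracle_breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    rs <- which(time >= t)
    dd <- which(time == t & event == 1)
    ll <- ll + beta * sum(x[dd]) - length(dd) * log(sum(exp(beta * x[rs])))
  }
  ll
}

# two-stage grid search maximizer of the Breslow partial likelihood
oracle_cox_grid <- function(time, event, x, lim = 3) {
  g1 <- seq(-lim, lim, by = 0.01)
  ll <- vapply(g1, oracle_breslow_loglik, numeric(1), time, event, x)
  b1 <- g1[which.max(ll)]
  g2 <- seq(b1 - 0.02, b1 + 0.02, by = 1e-5)
  ll2 <- vapply(g2, oracle_breslow_loglik, numeric(1), time, event, x)
  g2[which.max(ll2)]
}

# random small panel generator for oracle-equivalence sweeps
random_small_panel <- function(seed) {
  set.seed(seed)
  n_lines <- sample(4:10, 1)
  n_pw <- sample(2:5, 1)
  sizes <- sample(1:6, n_pw, replace = TRUE)
  map <- data.frame(
    metabolite = sprintf("m%02d", seq_len(sum(sizes))),
    pathway = rep(sprintf("pw%d", seq_len(n_pw)), sizes),
    stringsAsFactors = FALSE)
  mat <- matrix(stats::rnorm(sum(sizes) * n_lines), sum(sizes), n_lines,
                dimnames = list(map$metabolite, sprintf("L%02d", seq_len(n_lines))))
  resistance <- data.frame(cell_line = colnames(mat),
                           dmid = stats::runif(n_lines, 1, 8),
                           stringsAsFactors = FALSE)
  list(mat = mat, map = map, resistance = resistance)
}
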