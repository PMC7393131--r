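#' @title Pathway regulation scoring and radiosensitivity correlation
#' @description The core discovery computation: per-metabolite z-transform
#'   across cell lines, up/down regulation calls at the +/-1 thresholds,
#'   per-pathway regulation-fraction scores, Pearson correlation of pathway
#'   scores with the radiosensitivity orientation of the resistance score
#'   (Dmid), Benjamini-Hochberg FDR across pathways, and the
#'   post-irradiation fold-change variant of the whole cascade.
#' @name pathway_corr
NULL

#' Z-transform metabolite levels across cell lines
#'
#' Standardizes each metabolite row of a metabolite x cell_line matrix to zero
#' mean and unit variance (sample standard deviation, denominator n-1) across
#' cell lines.  Missing entries are handled by pairwise-complete
#' standardization over the available lines, with the effective n recorded.
#' Zero-variance metabolites are moved to `dropped` with a warning, never
#' emitted as z = 0.
#'
#' @param x metabolite x cell_line numeric matrix (replicate means), or a long
#'   metabolite_panel data.frame (collapsed via [panel_line_means()]).
#' @return object of class `zmatrix`: list with `z` (standardized matrix),
#'   `dropped` (metabolite ids excluded for zero variance or n < 2),
#'   `n_eff` (effective lines per retained metabolite).
#' @export
z_transform <- function(x) {
  if (is.data.frame(x)) x <- panel_line_means(x)
  if (!is.matrix(x)) stop("z_transform: need a metabolite x cell_line matrix or long panel")
  if (ncol(x) < 3) stop("sample-size error: z_transform needs >= 3 cell lines")
  mu <- rowMeans(x, na.rm = TRUE)
  n_eff <- rowSums(!is.na(x))
  sdv <- apply(x, 1L, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sdv) | sdv == 0 | n_eff < 2
  if (any(bad)) {
    warning(sprintf("z_transform: %d zero-variance or under-observed metabolite(s) dropped",
                    sum(bad)))
  }
  z <- (x - mu) / sdv
  structure(list(z = z[!bad, , drop = FALSE],
                 dropped = rownames(x)[bad],
                 n_eff = n_eff[!bad]),
            class = "zmatrix")
}

#' Up/down regulation calls from z-scores
#'
#' A metabolite is called downregulated in a cell line when its z-score is
#' strictly below `z_lower` and upregulated when strictly above `z_upper`
#' (defaults -1 / +1); boundary values are "none".
#'
#' @param z `zmatrix` from [z_transform()] (or a plain numeric matrix).
#' @param z_lower,z_upper call thresholds, `z_lower < z_upper`.
#' @return object of class `regulation_calls`: integer matrix (-1 = down,
#'   0 = none, +1 = up, NA = missing) with attribute `thresholds`.
#' @export
regulation_calls <- function(z, z_lower = -1, z_upper = 1) {
  if (!(z_lower < z_upper)) stop("configuration error: z_lower must be < z_upper")
  zm <- if (inherits(z, "zmatrix")) z$z else z
  calls <- matrix(0L, nrow(zm), ncol(zm), dimnames = dimnames(zm))
  calls[zm < z_lower] <- -1L
  calls[zm > z_upper] <- 1L
  calls[is.na(zm)] <- NA_integer_
  structure(calls, thresholds = c(z_lower = z_lower, z_upper = z_upper),
            class = c("regulation_calls", "matrix", "array"))
}

#' Per-pathway regulation-fraction scores
#'
#' For each (pathway, cell_line): down_score = number of metabolites called
#' down / number of the pathway's metabolites measured in that line (after QC
#' and variance filtering); up_score analogously.  Metabolites without a
#' pathway annotation are excluded with a logged count; a metabolite mapped to
#' more than one pathway is an error (single-membership annotation);
#' pathways with no measured metabolites are excluded with a warning.
#'
#' @param calls `regulation_calls` matrix.
#' @param pathway_map data.frame (metabolite, pathway).
#' @return data.frame of class `pathway_scores`: (pathway, cell_line,
#'   down_score, up_score, n_measured).
#' @export
pathway_scores <- function(calls, pathway_map) {
  pathway_map <- validate_table(pathway_map, "pathway_map",
                                source = attr(pathway_map, "source") %||% "in-memory")
  if (anyDuplicated(pathway_map$metabolite)) {
    stop("mapping error: metabolite mapped to more than one pathway")
  }
  mets <- rownames(calls)
  unmapped <- setdiff(mets, pathway_map$metabolite)
  if (length(unmapped)) {
    message(sprintf("pathway_scores: %d metabolite(s) without pathway annotation excluded",
                    length(unmapped)))
  }
  map <- pathway_map[pathway_map$metabolite %in% mets, , drop = FALSE]
  pathways <- unique(map$pathway)
  lines <- colnames(calls)
  rows <- vector("list", length(pathways))
  keep <- logical(length(pathways))
  for (k in seq_along(pathways)) {
    pw_mets <- map$metabolite[map$pathway == pathways[k]]
    sub <- calls[pw_mets, , drop = FALSE]
    n_meas <- colSums(!is.na(sub))
    if (all(n_meas == 0)) {
      warning(sprintf("pathway_scores: pathway '%s' has no measured metabolites; excluded",
                      pathways[k]))
      next
    }
    keep[k] <- TRUE
    n_down <- colSums(sub == -1L, na.rm = TRUE)
    n_up <- colSums(sub == 1L, na.rm = TRUE)
    rows[[k]] <- data.frame(
      pathway = pathways[k], cell_line = lines,
      down_score = ifelse(n_meas > 0, n_down / n_meas, NA_real_),
      up_score = ifelse(n_meas > 0, n_up / n_meas, NA_real_),
      n_measured = as.integer(n_meas),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  class(out) <- c("pathway_scores", "data.frame")
  out
}

#' Correlate pathway scores with radiosensitivity
#'
#' Pearson correlation, per pathway, of the chosen regulation-score vector
#' (down or up) against the sensitivity orientation of the resistance score:
#' sensitivity = -Dmid, so a positive r for a down-score means the pathway's
#' metabolites are depressed in radiosensitive lines.  Two-sided p-values come
#' from the t-distribution with n-2 degrees of freedom and q-values from
#' Benjamini-Hochberg step-up across all tested pathways (the chosen direction
#' is one family).  Pathways whose score vector has zero variance are reported
#' with missing r and excluded from the family.
#'
#' @param scores `pathway_scores` data.frame.
#' @param resistance data.frame (cell_line, dmid), dmid > 0.
#' @param direction `"down"` or `"up"`: which score to correlate.
#' @param orientation `"sensitivity"` (default, score vs -Dmid) or
#'   `"resistance"` (score vs Dmid).
#' @param p_threshold,fdr_threshold significance flags (defaults 0.05, 0.1).
#' @return data.frame (pathway, direction, n, r, p, q, significant) with
#'   attribute `orientation`.
#' @export
correlate_pathways <- function(scores, resistance,
                               direction = c("down", "up"),
                               orientation = c("sensitivity", "resistance"),
                               p_threshold = 0.05, fdr_threshold = 0.1) {
  direction <- match.arg(direction)
  orientation <- match.arg(orientation)
  resistance <- validate_table(resistance, "resistance",
                               source = attr(resistance, "source") %||% "in-memory")
  if (any(resistance$dmid <= 0)) stop("validation error: dmid must be > 0")
  lines <- intersect(unique(scores$cell_line), resistance$cell_line)
  if (length(lines) < 3) {
    stop("alignment error: fewer than 3 cell lines shared between scores and resistance")
  }
  target <- resistance$dmid[match(lines, resistance$cell_line)]
  if (orientation == "sensitivity") target <- -target
  scol <- if (direction == "down") "down_score" else "up_score"
  pathways <- unique(scores$pathway)
  res <- data.frame(pathway = pathways, direction = direction,
                    n = NA_integer_, r = NA_real_, p = NA_real_,
                    q = NA_real_, significant = NA, stringsAsFactors = FALSE)
  for (k in seq_along(pathways)) {
    sub <- scores[scores$pathway == pathways[k], , drop = FALSE]
    v <- sub[[scol]][match(lines, sub$cell_line)]
    ok <- is.finite(v) & is.finite(target)
    res$n[k] <- sum(ok)
    if (sum(ok) < 3 || stats::sd(v[ok]) == 0) next
    pr <- pearson_r_p(v[ok], target[ok])
    res$r[k] <- pr$r
    res$p[k] <- pr$p_value
  }
  tested <- !is.na(res$p)
  if (any(tested)) res$q[tested] <- bh_fdr(res$p[tested])
  res$significant <- !is.na(res$p) & res$p < p_threshold &
    !is.na(res$q) & res$q < fdr_threshold
  attr(res, "orientation") <- orientation
  res
}

#' Post-irradiation fold-change pathway analysis
#'
#' Runs the full scoring cascade on treated-vs-control fold changes: log2
#' transformation (symmetric treatment of up and down regulation), z-transform
#' across analysis units, regulation calls, pathway scores, and correlation of
#' the chosen direction with radiosensitivity.  Also returns group-averaged
#' fold changes per metabolite when a group assignment is supplied.
#'
#' @param fc result of [fold_change()] (list with `values`, `group_means`), or
#'   a data.frame (metabolite, cell_line, fold_change).
#' @param resistance data.frame (cell_line, dmid).
#' @param pathway_map data.frame (metabolite, pathway).
#' @param config `run_config` (thresholds and FDR cutoff).
#' @param direction score direction to correlate (default `"down"`, the
#'   post-irradiation depletion signature).
#' @return list with `zmatrix`, `calls`, `scores`, `correlations`,
#'   `group_means`.
#' @export
post_rt_pathway_analysis <- function(fc, resistance, pathway_map,
                                     config = run_config(),
                                     direction = "down") {
  vals <- if (is.data.frame(fc)) fc else fc$values
  group_means <- if (is.data.frame(fc)) NULL else fc$group_means
  if (!all(c("metabolite", "cell_line", "fold_change") %in% names(vals))) {
    stop("post_rt_pathway_analysis: fold-change table needs (metabolite, cell_line, fold_change)")
  }
  ok <- is.finite(vals$fold_change) & vals$fold_change > 0
  if (any(!ok)) {
    vals <- vals[ok, , drop = FALSE]
  }
  mets <- unique(vals$metabolite)
  lines <- unique(vals$cell_line)
  if (length(lines) < 3) stop("sample-size error: need fold changes for >= 3 analysis units")
  m <- matrix(NA_real_, length(mets), length(lines),
              dimnames = list(mets, lines))
  m[cbind(match(vals$metabolite, mets), match(vals$cell_line, lines))] <-
    log2(vals$fold_change)
  zm <- z_transform(m)
  if (nrow(zm$z) == 0) {
    warning("post_rt_pathway_analysis: all fold changes constant; empty result")
    return(list(zmatrix = zm, calls = NULL, scores = NULL,
                correlations = NULL, group_means = group_means))
  }
  calls <- regulation_calls(zm, config$z_lower, config$z_upper)
  scores <- pathway_scores(calls, pathway_map)
  correlations <- correlate_pathways(scores, resistance, direction = direction,
                                     fdr_threshold = config$fdr_threshold)
  list(zmatrix = zm, calls = calls, scores = scores,
       correlations = correlations, group_means = group_means)
}
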