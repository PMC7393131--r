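#' @title Metabolite panel quality control and preprocessing
#' @description QC of quantified LC-MS/MS metabolite panels: the ion-count
#'   detection threshold and replicate coefficient-of-variation filter, sample
#'   normalization, treated-vs-control fold changes, and stable-isotope
#'   fractional enrichment.
#' @name msprep
NULL

.panel_group_key <- function(panel) {
  paste(panel$metabolite, panel$cell_line, panel$condition, sep = "\r")
}

#' Ion-count and coefficient-of-variation QC filter
#'
#' Within each (metabolite, cell_line, condition) replicate group, the group is
#' set missing when its mean area falls below `min_ion_area` (detection
#' threshold, default 3000 ion counts) or when its coefficient of variation
#' sd/mean (sample standard deviation, denominator n-1) exceeds `max_cv`
#' (default 0.5).  A metabolite is then dropped entirely when missing in more
#' than `max_missing_frac` of its replicate groups.  The filter is idempotent:
#' groups already wholly missing are left missing without a new report entry.
#'
#' @param panel metabolite_panel data.frame (long format, replicate-annotated).
#' @param min_ion_area detection threshold in ion counts (>= 0).
#' @param max_cv maximum replicate CV (> 0).
#' @param max_missing_frac metabolite drop rule (default 0.5).
#' @return list with `panel` (filtered; failed groups have `area = NA`,
#'   dropped metabolites removed) and `report` (data.frame: metabolite,
#'   cell_line, condition, action, reason).
#' @export
qc_filter <- function(panel, min_ion_area = 3000, max_cv = 0.5,
                      max_missing_frac = 0.5) {
  panel <- validate_table(panel, "metabolite_panel",
                          source = attr(panel, "source") %||% "in-memory")
  if (all(is.na(panel$replicate))) {
    stop("configuration error: qc_filter requires replicate annotations")
  }
  if (min_ion_area < 0) stop("qc_filter: min_ion_area must be >= 0")
  if (max_cv <= 0) stop("qc_filter: max_cv must be > 0")

  key <- .panel_group_key(panel)
  groups <- split(seq_len(nrow(panel)), key)
  rep_rows <- list()
  for (idx in groups) {
    areas <- panel$area[idx]
    if (all(is.na(areas))) next  # already missing: leave untouched
    mu <- mean(areas, na.rm = TRUE)
    cv <- if (sum(!is.na(areas)) > 1) stats::sd(areas, na.rm = TRUE) / mu else 0
    reason <- NULL
    if (mu < min_ion_area) {
      reason <- sprintf("mean area %.6g below detection threshold %g", mu, min_ion_area)
    } else if (is.finite(cv) && cv > max_cv) {
      reason <- sprintf("replicate CV %.4g above %g", cv, max_cv)
    }
    if (!is.null(reason)) {
      panel$area[idx] <- NA_real_
      i <- idx[1]
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        metabolite = panel$metabolite[i], cell_line = panel$cell_line[i],
        condition = panel$condition[i], action = "group_set_missing",
        reason = reason, stringsAsFactors = FALSE)
    }
  }

  # metabolite drop rule: missing in more than max_missing_frac of groups
  key <- .panel_group_key(panel)
  grp_missing <- tapply(panel$area, key, function(a) all(is.na(a)))
  grp_met <- vapply(strsplit(names(grp_missing), "\r", fixed = TRUE),
                    `[`, character(1), 1L)
  miss_frac <- tapply(as.numeric(grp_missing), grp_met, mean)
  drop_mets <- names(miss_frac)[miss_frac > max_missing_frac]
  if (length(drop_mets)) {
    for (m in drop_mets) {
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        metabolite = m, cell_line = NA_character_, condition = NA_character_,
        action = "metabolite_dropped",
        reason = sprintf("missing in %.0f%% of replicate groups (> %.0f%%)",
                         100 * miss_frac[[m]], 100 * max_missing_frac),
        stringsAsFactors = FALSE)
    }
    panel <- panel[!(panel$metabolite %in% drop_mets), , drop = FALSE]
  }
  if (nrow(panel) == 0 || all(is.na(panel$area))) {
    stop("empty-panel error: QC removed every metabolite")
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(metabolite = character(0), cell_line = character(0),
               condition = character(0), action = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  panel <- validate_table(panel, "metabolite_panel",
                          source = attr(panel, "source") %||% "in-memory")
  list(panel = panel, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample normalization
#'
#' Divides each sample's intensities by a per-sample factor.  Methods:
#' `none` (identity, the default for the pipeline since the acquisition-side
#' normalization basis is usually unstated), `total_signal` (factor
#' proportional to the sample's total area, scaled so post-normalization
#' totals all equal the grand mean total), `median` (same with per-sample
#' medians), `reference_sample` (factor = median ratio of the sample to a
#' named reference sample over shared metabolites).
#'
#' @param panel metabolite_panel data.frame.
#' @param method one of `"none"`, `"total_signal"`, `"median"`,
#'   `"reference_sample"`.
#' @param reference sample id, required for `method = "reference_sample"`.
#' @return normalized panel with attribute `norm_factors`
#'   (data.frame: sample, factor, method).
#' @export
normalize_samples <- function(panel,
                              method = c("none", "total_signal", "median",
                                         "reference_sample"),
                              reference = NULL) {
  method <- match.arg(method)
  panel <- validate_table(panel, "metabolite_panel",
                          source = attr(panel, "source") %||% "in-memory")
  samples <- unique(panel$sample)
  if (method == "none") {
    factors <- rep(1, length(samples))
  } else if (method %in% c("total_signal", "median")) {
    stat <- vapply(samples, function(s) {
      a <- panel$area[panel$sample == s]
      if (all(is.na(a))) NA_real_
      else if (method == "total_signal") sum(a, na.rm = TRUE)
      else stats::median(a, na.rm = TRUE)
    }, numeric(1))
    bad <- samples[!is.finite(stat) | stat <= 0]
    if (length(bad)) {
      stop(sprintf("normalization error: non-positive or undefined %s for sample '%s'",
                   method, bad[1]))
    }
    factors <- stat / mean(stat)
  } else {
    if (is.null(reference) || !(reference %in% samples)) {
      stop("normalization error: reference_sample method needs a valid 'reference' sample id")
    }
    ref <- panel[panel$sample == reference, c("metabolite", "area")]
    factors <- vapply(samples, function(s) {
      cur <- panel[panel$sample == s, c("metabolite", "area")]
      m <- merge(cur, ref, by = "metabolite", suffixes = c("", "_ref"))
      ratio <- m$area / m$area_ref
      stats::median(ratio[is.finite(ratio) & ratio > 0])
    }, numeric(1))
    bad <- samples[!is.finite(factors) | factors <= 0]
    if (length(bad)) {
      stop(sprintf("normalization error: non-positive factor for sample '%s'", bad[1]))
    }
  }
  fac <- stats::setNames(factors, samples)
  panel$area <- panel$area / fac[panel$sample]
  attr(panel, "norm_factors") <- data.frame(sample = samples,
                                            factor = unname(factors),
                                            method = method,
                                            stringsAsFactors = FALSE)
  panel
}

#' Treated-vs-control fold changes, with optional group averaging
#'
#' Per metabolite and cell line: fold change = mean(treated replicate areas) /
#' mean(control replicate areas), matched within the same cell line.  When a
#' group assignment is supplied (e.g. "resistant" vs "sensitive" lines), the
#' per-line fold changes are additionally arithmetically averaged within each
#' group.
#'
#' @param panel metabolite_panel data.frame containing both conditions.
#' @param treated_condition,control_condition condition labels.
#' @param groups optional named list mapping group label -> cell line ids.
#' @return list with `values` (data.frame: metabolite, cell_line, fold_change)
#'   and `group_means` (data.frame: metabolite, group, mean_fold_change; NULL
#'   when `groups` is not given).
#' @export
fold_change <- function(panel, treated_condition, control_condition,
                        groups = NULL) {
  panel <- validate_table(panel, "metabolite_panel",
                          source = attr(panel, "source") %||% "in-memory")
  lines <- unique(panel$cell_line)
  for (cl in lines) {
    conds <- unique(panel$condition[panel$cell_line == cl])
    if (!(treated_condition %in% conds) || !(control_condition %in% conds)) {
      stop(sprintf("pairing error: cell line '%s' lacks condition '%s'",
                   cl, setdiff(c(treated_condition, control_condition), conds)[1]))
    }
  }
  grp_mean <- function(cond) {
    sub <- panel[panel$condition == cond, , drop = FALSE]
    key <- paste(sub$metabolite, sub$cell_line, sep = "\r")
    tapply(sub$area, key, mean, na.rm = TRUE)
  }
  mt <- grp_mean(treated_condition)
  mc <- grp_mean(control_condition)
  keys <- intersect(names(mt), names(mc))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  vals <- data.frame(
    metabolite = vapply(parts, `[`, character(1), 1L),
    cell_line = vapply(parts, `[`, character(1), 2L),
    fold_change = unname(mt[keys] / mc[keys]),
    stringsAsFactors = FALSE)
  bad <- !is.na(mc[keys]) & mc[keys] <= 0
  if (any(bad, na.rm = TRUE)) {
    warning(sprintf("fold_change: %d control mean(s) <= 0; values set missing",
                    sum(bad, na.rm = TRUE)))
    vals$fold_change[bad] <- NA_real_
  }
  vals$fold_change[!is.finite(vals$fold_change)] <- NA_real_
  group_means <- NULL
  if (!is.null(groups)) {
    rows <- list()
    for (g in names(groups)) {
      sub <- vals[vals$cell_line %in% groups[[g]], , drop = FALSE]
      gm <- tapply(sub$fold_change, sub$metabolite, mean, na.rm = TRUE)
      rows[[g]] <- data.frame(metabolite = names(gm), group = g,
                              mean_fold_change = unname(gm),
                              stringsAsFactors = FALSE)
    }
    group_means <- do.call(rbind, rows)
    rownames(group_means) <- NULL
  }
  list(values = vals, group_means = group_means)
}

#' Stable-isotope fractional enrichment
#'
#' Labeled fraction per metabolite = sum of areas of isotopologues M+1 and
#' above, divided by the total isotopologue area.  No natural-abundance
#' correction is applied; the result is the raw labeled fraction.
#'
#' @param iso isotopologue data.frame (metabolite, isotopologue index >= 0,
#'   area).
#' @return named numeric vector, labeled fraction in \[0, 1\] per metabolite
#'   (NA when the total area is zero).
#' @export
fractional_enrichment <- function(iso) {
  iso <- validate_table(iso, "isotopologue",
                        source = attr(iso, "source") %||% "in-memory")
  if (any(iso$area < 0, na.rm = TRUE)) {
    stop("validation error: negative isotopologue area")
  }
  if (any(iso$isotopologue < 0 | iso$isotopologue != round(iso$isotopologue))) {
    stop("validation error: isotopologue indices must be non-negative integers")
  }
  mets <- unique(iso$metabolite)
  out <- vapply(mets, function(m) {
    sub <- iso[iso$metabolite == m, , drop = FALSE]
    if (!any(sub$isotopologue == 0)) {
      stop(sprintf("validation error: metabolite '%s' lacks an M+0 record", m))
    }
    tot <- sum(sub$area, na.rm = TRUE)
    if (!is.finite(tot) || tot <= 0) return(NA_real_)
    sum(sub$area[sub$isotopologue >= 1], na.rm = TRUE) / tot
  }, numeric(1))
  stats::setNames(out, mets)
}

#' Replicate-mean matrix view of a metabolite panel
#'
#' Collapses a long panel to a metabolite x cell_line matrix of replicate-mean
#' areas for one condition — the in-memory wide view consumed by the
#' z-transform.
#'
#' @param panel metabolite_panel data.frame.
#' @param condition condition to extract (default: the panel's only condition).
#' @return numeric matrix, rownames = metabolites, colnames = cell lines.
#' @export
panel_line_means <- function(panel, condition = NULL) {
  panel <- validate_table(panel, "metabolite_panel",
                          source = attr(panel, "source") %||% "in-memory")
  if (is.null(condition)) {
    conds <- unique(panel$condition)
    if (length(conds) != 1) {
      stop("panel_line_means: panel has multiple conditions; specify one")
    }
    condition <- conds
  }
  sub <- panel[panel$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0) stop(sprintf("panel_line_means: no rows for condition '%s'", condition))
  mets <- unique(sub$metabolite)
  lines <- unique(sub$cell_line)
  m <- matrix(NA_real_, length(mets), length(lines),
              dimnames = list(mets, lines))
  key <- paste(sub$metabolite, sub$cell_line, sep = "\r")
  means <- tapply(sub$area, key, mean, na.rm = TRUE)
  parts <- strsplit(names(means), "\r", fixed = TRUE)
  mi <- match(vapply(parts, `[`, character(1), 1L), mets)
  li <- match(vapply(parts, `[`, character(1), 2L), lines)
  m[cbind(mi, li)] <- unname(means)
  m[is.nan(m)] <- NA_real_
  m
}
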