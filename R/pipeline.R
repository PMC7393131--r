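#' @title Pipeline orchestrator
#' @description Deterministic end-to-end driver: reads and validates the
#'   declared inputs, runs QC, pathway scoring, correlation and FDR (and the
#'   radioresponse and endpoint stages when their inputs are supplied), writes
#'   every result table with reproducible formatting, and records a manifest
#'   (full effective config, input checksums, package version) sufficient to
#'   re-run the analysis.
#' @name pipeline
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Required input roles: `metabolite_panel`, `pathway_map`, and either
#' `resistance` (cell_line, dmid) or `clonogenic` (per-line assays from which
#' Dmid is fitted).  Optional roles: `growth` (tripling-time endpoint
#' analysis), `survival` (per-arm Kaplan-Meier and log-rank), and
#' `expression_survival` (median-split survival with Cox HR).  All stages are
#' deterministic given the config; any stage error aborts the run, removes
#' partial outputs, and names the failing stage.
#'
#' @param config `run_config` object.
#' @param inputs named character vector/list mapping role -> input file path.
#' @param out_dir output directory (created if absent).
#' @return named list mapping output role -> written file path (invisibly the
#'   same list carries the in-memory results as attribute `results`).
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  stopifnot(inherits(config, "run_config"))
  inputs <- as.list(inputs)
  required <- c("metabolite_panel", "pathway_map")
  for (role in required) {
    if (is.null(inputs[[role]])) {
      stop(sprintf("pipeline input error: missing required role '%s'", role))
    }
  }
  if (is.null(inputs$resistance) && is.null(inputs$clonogenic)) {
    stop("pipeline input error: need a 'resistance' or 'clonogenic' input")
  }
  for (role in names(inputs)) {
    if (!file.exists(inputs[[role]])) {
      stop(sprintf("pipeline input error: role '%s' file not found: %s",
                   role, inputs[[role]]))
    }
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- list()
  written <- character(0)
  on_fail_cleanup <- function() unlink(written)
  emit <- function(role, table) {
    path <- file.path(out_dir, paste0(role, ".tsv"))
    write_table(table, path)
    written <<- c(written, path)
    outputs[[role]] <<- path
  }

  results <- list()
  ok <- FALSE
  on.exit(if (!ok) on_fail_cleanup())

  panel <- .stage("read_inputs",
                  read_long_table(inputs$metabolite_panel, "metabolite_panel"))
  pathway_map <- .stage("read_inputs",
                        read_long_table(inputs$pathway_map, "pathway_map"))

  resistance <- if (!is.null(inputs$resistance)) {
    .stage("read_inputs", read_long_table(inputs$resistance, "resistance"))
  } else {
    clono <- .stage("read_inputs", read_long_table(inputs$clonogenic, "clonogenic"))
    .stage("radioresponse", {
      fits <- lapply(split(clono, clono$cell_line), function(sub) {
        crv <- fit_survival_curve(sub, dose_max = config$dose_max)
        data.frame(cell_line = sub$cell_line[1], treatment = sub$treatment[1],
                   alpha = crv$alpha, beta = crv$beta, dmid = crv$dmid_fitted,
                   stringsAsFactors = FALSE)
      })
      fits <- do.call(rbind, fits)
      rownames(fits) <- NULL
      emit("lq_fits", fits)
      fits[, c("cell_line", "dmid")]
    })
  }

  set.seed(config$seed)
  qc <- .stage("qc", {
    if (config$normalization != "none") {
      panel <- normalize_samples(panel, config$normalization)
    }
    qc_filter(panel, config$min_ion_area, config$max_cv,
              config$max_missing_frac)
  })
  emit("qc_report", qc$report)

  scored <- .stage("scoring", {
    zm <- z_transform(panel_line_means(qc$panel))
    calls <- regulation_calls(zm, config$z_lower, config$z_upper)
    pathway_scores(calls, pathway_map)
  })
  emit("pathway_scores", scored)

  corr <- .stage("correlation", {
    rbind(correlate_pathways(scored, resistance, "down",
                             fdr_threshold = config$fdr_threshold),
          correlate_pathways(scored, resistance, "up",
                             fdr_threshold = config$fdr_threshold))
  })
  emit("pathway_correlations", corr)
  # two-column export consumable by external pathway-map renderers
  sig <- corr[!is.na(corr$r), c("pathway", "r")]
  names(sig) <- c("pathway", "score")
  emit("pathway_map_export", sig)
  results$pathway_scores <- scored
  results$pathway_correlations <- corr

  if (!is.null(inputs$growth)) {
    growth <- .stage("read_inputs", read_long_table(inputs$growth, "growth"))
    .stage("endpoints_growth", {
      tr <- tripling_records(growth)
      emit("tripling", tr[, c("animal", "arm", "tripling_day", "censored", "last_day")])
      ep <- arm_endpoint_analysis(tr$time, tr$event, tr$arm)
      emit("endpoint_summary", ep$summary)
      emit("pairwise_tests", ep$pairwise)
      results$tripling <- tr
      results$endpoints <- ep
    })
  }
  if (!is.null(inputs$survival)) {
    surv <- .stage("read_inputs", read_long_table(inputs$survival, "survival"))
    .stage("endpoints_survival", {
      ep <- arm_endpoint_analysis(surv$time_days, surv$event, surv$group)
      emit("survival_summary", ep$summary)
      emit("survival_pairwise", ep$pairwise)
      results$survival_endpoints <- ep
    })
  }
  if (!is.null(inputs$expression_survival)) {
    es <- .stage("read_inputs",
                 read_long_table(inputs$expression_survival, "expression_survival"))
    .stage("median_split", {
      ms <- median_split_survival(es$expression, es$os_days, es$os_event)
      tab <- data.frame(
        comparison = "high vs low (median split)",
        statistic = ms$logrank$statistic, df_or_n = ms$logrank$df,
        p = ms$logrank$p_value, hr = ms$cox$hr,
        ci_low = ms$cox$ci_low, ci_high = ms$cox$ci_high,
        stringsAsFactors = FALSE)
      emit("median_split", tab)
      results$median_split <- ms
    })
  }

  manifest <- list(
    package = "radiometab",
    version = as.character(utils::packageVersion("radiometab")),
    config = unclass(config),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    outputs = outputs
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  written <- c(written, manifest_path)
  outputs$manifest <- manifest_path
  ok <- TRUE
  structure(outputs, results = results)
}
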