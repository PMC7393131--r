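#' @title Synthetic-data generators with recorded ground truth
#' @description Pure-function generators (deterministic given their seed) for
#'   every input the pipeline consumes: a cell-line metabolite panel whose
#'   chosen pathway is coupled to a latent radiosensitivity score, Poisson
#'   colony counts from linear-quadratic survival, exponentially growing tumor
#'   cohorts with multiplicative treatment effects, and exponential survival
#'   cohorts with a group hazard ratio.  Each generator returns the generating
#'   parameters (`truth`) so downstream stages can be tested by parameter
#'   recovery.
#' @name synthetic_data
NULL

#' Bundled synthetic pathway annotation
#'
#' A single-membership metabolite-to-pathway map covering the purine,
#' pyrimidine, glutathione and nucleotide-sugar families the pipeline scores:
#' guanylates, adenylates, inosinates, cytidine, glutathione, nucleotide_sugar
#' (30 synthetic metabolites in all).
#'
#' @return data.frame (metabolite, pathway).
#' @export
default_pathway_map <- function() {
  map <- list(
    guanylates = c("GMP", "GDP", "GTP", "cGMP", "guanosine", "guanine"),
    adenylates = c("AMP", "ADP", "ATP", "cAMP", "adenosine", "adenine"),
    inosinates = c("IMP", "inosine", "hypoxanthine", "xanthine"),
    cytidine = c("CMP", "CDP", "CTP", "cytidine"),
    glutathione = c("GSH", "GSSG", "cysteine", "gamma-glutamylcysteine",
                    "cysteinylglycine"),
    nucleotide_sugar = c("UDP-glucose", "UDP-galactose", "UDP-GlcNAc",
                         "GDP-mannose", "CMP-sialate")
  )
  df <- data.frame(
    metabolite = unlist(map, use.names = FALSE),
    pathway = rep(names(map), lengths(map)),
    stringsAsFactors = FALSE)
  validate_table(df, "pathway_map", source = "default_pathway_map()")
}

.sizes_to_map <- function(pathways) {
  if (is.data.frame(pathways)) return(pathways)
  mets <- unlist(lapply(names(pathways), function(p) {
    sprintf("%s_met%02d", p, seq_len(pathways[[p]]))
  }))
  data.frame(metabolite = mets,
             pathway = rep(names(pathways), unlist(pathways)),
             stringsAsFactors = FALSE)
}

#' Simulate a radiosensitivity-coupled metabolite panel
#'
#' Draws a per-line Dmid from a uniform range, standardizes it to a latent
#' radiosensitivity score, and generates log-intensities: metabolites of the
#' coupled pathway follow `r_true * s + sqrt(1 - r_true^2) * N(0, 1)` per line
#' (population correlation of the metabolite level with Dmid equal to
#' `r_true`), all other metabolites are independent `N(0, noise_sd^2)`.
#' Replicate-level areas add lognormal measurement noise and are exponentiated
#' to positive intensities on a baseline well above the ion-count detection
#' threshold.
#'
#' @param n_lines number of cell lines (default 23, the panel design).
#' @param pathways pathway map data.frame or named vector of pathway sizes;
#'   default [default_pathway_map()].
#' @param coupled_pathway pathway whose metabolites track radiosensitivity;
#'   `NA` for a global-null panel.
#' @param r_true generating coupling in (-1, 1) (default 0.8).
#' @param noise_sd log-scale sd of uncoupled metabolites (default 1).
#' @param replicates technical replicates per line (default 3).
#' @param seed integer seed.
#' @param dmid_range uniform range (Gy) for the true Dmid (default 2-6 Gy,
#'   the span observed across glioblastoma panels assayed to 8 Gy).
#' @param base_log_area baseline log intensity (default log(5e4) ion counts).
#' @param replicate_sd log-scale replicate measurement noise (default 0.1).
#' @return list: `panel` (long metabolite_panel data.frame), `resistance`
#'   (cell_line, dmid), `line_means` (metabolite x line matrix of generating
#'   log-level means, before replicate noise), `truth` (generating
#'   parameters).
#' @export
simulate_metabolite_panel <- function(n_lines = 23,
                                      pathways = default_pathway_map(),
                                      coupled_pathway = "guanylates",
                                      r_true = 0.8, noise_sd = 1,
                                      replicates = 3, seed = 1L,
                                      dmid_range = c(2, 6),
                                      base_log_area = log(5e4),
                                      replicate_sd = 0.1) {
  if (n_lines < 3) stop("simulate_metabolite_panel: n_lines must be >= 3")
  if (!is.na(r_true) && abs(r_true) >= 1) stop("r_true must be in (-1, 1)")
  map <- .sizes_to_map(pathways)
  if (!is.na(coupled_pathway) && !(coupled_pathway %in% map$pathway)) {
    stop(sprintf("configuration error: coupled pathway '%s' not in the pathway map",
                 coupled_pathway))
  }
  set.seed(seed)
  dmid <- stats::runif(n_lines, dmid_range[1], dmid_range[2])
  lines <- sprintf("line%02d", seq_len(n_lines))
  s <- as.numeric(scale(dmid))
  mets <- map$metabolite
  coupled <- !is.na(coupled_pathway) & map$pathway == coupled_pathway
  n_met <- length(mets)
  latent <- matrix(NA_real_, n_met, n_lines, dimnames = list(mets, lines))
  for (i in seq_len(n_met)) {
    latent[i, ] <- if (coupled[i]) {
      r_true * s + sqrt(1 - r_true^2) * stats::rnorm(n_lines)
    } else {
      noise_sd * stats::rnorm(n_lines)
    }
  }
  reps <- seq_len(replicates)
  idx <- expand.grid(rep = reps, line = seq_len(n_lines), met = seq_len(n_met))
  log_area <- base_log_area + latent[cbind(idx$met, idx$line)] +
    stats::rnorm(nrow(idx), sd = replicate_sd)
  panel <- data.frame(
    metabolite = mets[idx$met],
    sample = sprintf("%s_r%d", lines[idx$line], idx$rep),
    cell_line = lines[idx$line],
    condition = "basal",
    replicate = idx$rep,
    area = exp(log_area),
    stringsAsFactors = FALSE)
  resistance <- data.frame(cell_line = lines, dmid = dmid,
                           stringsAsFactors = FALSE)
  list(panel = validate_table(panel, "metabolite_panel", "simulate_metabolite_panel()"),
       resistance = validate_table(resistance, "resistance", "simulate_metabolite_panel()"),
       line_means = latent,
       truth = list(seed = seed, n_lines = n_lines,
                    coupled_pathway = coupled_pathway, r_true = r_true,
                    noise_sd = noise_sd, replicates = replicates,
                    dmid = dmid, dmid_range = dmid_range,
                    replicate_sd = replicate_sd))
}

#' Simulate a clonogenic assay under linear-quadratic survival
#'
#' Colony counts per replicate are Poisson with mean
#' `cells_plated * pe * exp(-(alpha*d + beta*d^2))`.
#'
#' @param alpha,beta linear-quadratic parameters (1/Gy, 1/Gy^2), >= 0.
#' @param pe plating efficiency in (0, 1].
#' @param cells_plated cells plated per replicate (may be a vector matched to
#'   `doses` to plate more cells at higher dose).
#' @param doses dose schedule (Gy) including 0.
#' @param replicates replicates per dose (default 3).
#' @param seed integer seed.
#' @param cell_line,treatment labels for the output table.
#' @return list: `assay` (clonogenic data.frame), `truth`.
#' @export
simulate_clonogenic_assay <- function(alpha, beta, pe = 0.8,
                                      cells_plated = 500,
                                      doses = c(0, 2, 4, 6, 8),
                                      replicates = 3, seed = 1L,
                                      cell_line = "synthline",
                                      treatment = "control") {
  if (!(pe > 0 && pe <= 1)) stop("simulate_clonogenic_assay: pe must be in (0, 1]")
  if (!any(doses == 0)) stop("simulate_clonogenic_assay: doses must include 0")
  if (alpha < 0 || beta < 0) stop("simulate_clonogenic_assay: alpha, beta must be >= 0")
  plated <- rep_len(cells_plated, length(doses))
  mu <- plated * pe * exp(-(alpha * doses + beta * doses^2))
  if (any(mu > plated)) stop("parameterization error: expected colonies exceed cells plated")
  set.seed(seed)
  rows <- lapply(seq_along(doses), function(i) {
    data.frame(cell_line = cell_line, treatment = treatment,
               dose_gy = doses[i], cells_plated = plated[i],
               colonies = stats::rpois(replicates, mu[i]),
               replicate = seq_len(replicates), stringsAsFactors = FALSE)
  })
  assay <- do.call(rbind, rows)
  list(assay = validate_table(assay, "clonogenic", "simulate_clonogenic_assay()"),
       truth = list(alpha = alpha, beta = beta, pe = pe,
                    cells_plated = cells_plated, doses = doses,
                    replicates = replicates, seed = seed))
}

#' Simulate an exponentially growing tumor cohort
#'
#' Per animal and day: `V(t) = baseline * exp(rate * t) * exp(N(0, noise_sd))`
#' (lognormal multiplicative noise, positivity-preserving).  Arm-specific
#' growth rates encode treatment effects.
#'
#' @param arms named numeric vector: arm label -> daily growth rate (1/day).
#' @param n_per_arm animals per arm (default 10, i.e. ten tumors per group).
#' @param baseline_mm3 starting volume (default 90 mm^3, the randomization
#'   size window).
#' @param noise_sd log-scale measurement noise (default 0.1).
#' @param days measurement schedule (default days 1 to 33, three times weekly:
#'   1, 3, 5, 8, ...).
#' @param seed integer seed.
#' @return list: `growth` (data.frame animal, arm, day, volume_mm3), `truth`.
#' @export
simulate_growth_cohort <- function(arms, n_per_arm = 10, baseline_mm3 = 90,
                                   noise_sd = 0.1,
                                   days = c(1, 3, 5, 8, 10, 12, 15, 17, 19,
                                            22, 24, 26, 29, 31, 33),
                                   seed = 1L) {
  if (n_per_arm < 1) stop("configuration error: n_per_arm must be >= 1")
  if (is.null(names(arms)) || any(names(arms) == "")) {
    stop("simulate_growth_cohort: arms must be a named rate vector")
  }
  if (is.unsorted(days, strictly = TRUE)) stop("days must be strictly increasing")
  set.seed(seed)
  rows <- list()
  for (a in names(arms)) {
    for (i in seq_len(n_per_arm)) {
      noise <- stats::rnorm(length(days), sd = noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        animal = sprintf("%s_%02d", a, i), arm = a, day = days,
        volume_mm3 = baseline_mm3 * exp(arms[[a]] * days) * exp(noise),
        stringsAsFactors = FALSE)
    }
  }
  growth <- do.call(rbind, rows)
  rownames(growth) <- NULL
  list(growth = validate_table(growth, "growth", "simulate_growth_cohort()"),
       truth = list(arms = arms, n_per_arm = n_per_arm,
                    baseline_mm3 = baseline_mm3, noise_sd = noise_sd,
                    days = days, seed = seed))
}

#' Simulate an exponential survival cohort with a group hazard ratio
#'
#' Event times are exponential with hazard `baseline_hazard` in the reference
#' ("low") group and `baseline_hazard * hr` in the indexed ("high") group,
#' administratively censored at `censor_day`.  Optionally attaches expression
#' values separated by group (high-expression subjects are the hazard-ratio
#' group), yielding an expression-survival table for median-split analysis.
#'
#' @param n_per_group subjects per group (default 104, a 208-patient cohort).
#' @param baseline_hazard events/day, > 0 (default log(2)/42: 42-day median).
#' @param hr hazard ratio of the high group vs baseline, > 0.
#' @param censor_day administrative censoring time (default Inf = none).
#' @param seed integer seed.
#' @param expression if TRUE also return an expression_survival table with
#'   group-separated expression values.
#' @return list: `events` (data.frame subject, group, time_days, event),
#'   optional `expression_survival`, `truth`.
#' @export
simulate_survival_cohort <- function(n_per_group = 104,
                                     baseline_hazard = log(2) / 42,
                                     hr = 0.6, censor_day = Inf, seed = 1L,
                                     expression = FALSE) {
  if (!(baseline_hazard > 0)) stop("simulate_survival_cohort: hazard must be > 0")
  if (!(hr > 0)) stop("simulate_survival_cohort: hr must be > 0")
  if (!(censor_day > 0)) stop("configuration error: censor_day must be > 0")
  set.seed(seed)
  group <- rep(c("low", "high"), each = n_per_group)
  hazard <- ifelse(group == "high", baseline_hazard * hr, baseline_hazard)
  t_event <- stats::rexp(2 * n_per_group, rate = hazard)
  time <- pmin(t_event, censor_day)
  event <- as.integer(t_event <= censor_day)
  events <- data.frame(subject = sprintf("s%03d", seq_along(group)),
                       group = group, time_days = time, event = event,
                       stringsAsFactors = FALSE)
  out <- list(events = validate_table(events, "survival",
                                      "simulate_survival_cohort()"),
              truth = list(n_per_group = n_per_group,
                           baseline_hazard = baseline_hazard, hr = hr,
                           censor_day = censor_day, seed = seed))
  if (expression) {
    expr <- ifelse(group == "high", 2, 0) + stats::rnorm(length(group), sd = 0.5)
    es <- data.frame(patient = events$subject, gene = "synthgene",
                     expression = expr, os_days = time, os_event = event,
                     stringsAsFactors = FALSE)
    out$expression_survival <- validate_table(es, "expression_survival",
                                              "simulate_survival_cohort()")
  }
  out
}
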