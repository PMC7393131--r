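test_that("read_long_table validates schema, keys and numerics", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "panel.csv")
  writeLines(c("metabolite,sample,cell_line,condition,replicate,area",
               "GMP,s1,L1,basal,1,1200",
               "GMP,s2,L1,basal,2,1300"), p)
  tab <- read_long_table(p, "metabolite_panel")
  expect_equal(nrow(tab), 2)
  expect_type(tab$area, "double")
  expect_equal(attr(tab, "schema_name"), "metabolite_panel")

  empty <- file.path(dir, "empty.csv")
  file.create(empty)
  expect_error(read_long_table(empty, "metabolite_panel"), "schema error")

  dup <- file.path(dir, "dup.csv")
  writeLines(c("metabolite,sample,cell_line,condition,replicate,area",
               "GMP,s1,L1,basal,1,1200",
               "GMP,s1,L1,basal,1,1300"), dup)
  expect_error(read_long_table(dup, "metabolite_panel"), "integrity error")

  mis <- file.path(dir, "mis.csv")
  writeLines(c("metabolite,sample,cell_line,area", "GMP,s1,L1,1200"), mis)
  expect_error(read_long_table(mis, "metabolite_panel"), "condition")

  bad <- file.path(dir, "bad.csv")
  writeLines(c("metabolite,sample,cell_line,condition,replicate,area",
               "GMP,s1,L1,basal,1,12x0"), bad)
  expect_error(read_long_table(bad, "metabolite_panel"), "parse error.*row 1")
})

test_that("write_table round-trips, preserves missing values, is byte-stable", {
  dir <- withr::local_tempdir()
  tab <- data.frame(pathway = c("guanylates", "adenylates", "cytidine"),
                    cell_line = c("L1", "L1", "L2"),
                    down_score = c(0.5, NA, 1 / 3),
                    up_score = c(0.25, 0, 0),
                    n_measured = c(4L, 6L, 3L),
                    stringsAsFactors = FALSE)
  p1 <- file.path(dir, "a.tsv"); p2 <- file.path(dir, "b.tsv")
  write_table(tab, p1)
  back <- read_long_table(p1, "pathway_scores")
  expect_equal(back$down_score, tab$down_score, tolerance = 1e-6)
  expect_true(is.na(back$down_score[2]))
  expect_equal(back$n_measured, tab$n_measured)
  # empty-field encoding, never the string NA
  raw <- readLines(p1)
  expect_false(any(grepl("\tNA\t|\tNA$", raw)))
  write_table(back, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  suppressWarnings(
    expect_error(write_table(tab, file.path(dir, "no_such_dir", "x.tsv"))))
})

test_that("run_config enforces its invariants and reads from YAML/JSON", {
  cfg <- run_config()
  expect_equal(cfg$min_ion_area, 3000)
  expect_equal(cfg$max_cv, 0.5)
  expect_equal(c(cfg$z_lower, cfg$z_upper), c(-1, 1))
  expect_equal(cfg$fdr_threshold, 0.1)
  expect_error(run_config(z_lower = 1, z_upper = -1), "z_lower")
  expect_error(run_config(max_cv = 0), "max_cv")
  expect_error(run_config(fdr_threshold = 1.5), "fdr_threshold")
  expect_error(run_config(dose_max = -2), "dose_max")

  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("min_ion_area: 2500", "seed: 99"), yml)
  cfg <- read_run_config(yml)
  expect_equal(cfg$min_ion_area, 2500)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$max_cv, 0.5)  # defaults filled in
  jsn <- file.path(dir, "cfg.json")
  writeLines('{"fdr_threshold": 0.05}', jsn)
  expect_equal(read_run_config(jsn)$fdr_threshold, 0.05)
  writeLines("bogus_field: 3", yml)
  expect_error(read_run_config(yml), "unknown field")
})

test_that("run_pipeline orchestrates QC -> scoring -> correlation deterministically", {
  dir <- withr::local_tempdir()
  sim <- simulate_metabolite_panel(seed = 21)
  panel_path <- file.path(dir, "panel.tsv")
  map_path <- file.path(dir, "map.tsv")
  res_path <- file.path(dir, "resistance.tsv")
  write_table(sim$panel, panel_path)
  write_table(default_pathway_map(), map_path)
  write_table(sim$resistance, res_path)
  inputs <- c(metabolite_panel = panel_path, pathway_map = map_path,
              resistance = res_path)

  out1 <- run_pipeline(run_config(seed = 5), inputs, file.path(dir, "run1"))
  expect_true(file.exists(out1$pathway_scores))
  expect_true(file.exists(out1$pathway_correlations))
  manifest <- jsonlite::read_json(out1$manifest)
  expect_equal(manifest$config$seed, 5)
  expect_equal(length(manifest$inputs), 3)

  out2 <- run_pipeline(run_config(seed = 5), inputs, file.path(dir, "run2"))
  for (role in c("pathway_scores", "pathway_correlations", "qc_report")) {
    expect_identical(unname(tools::md5sum(out1[[role]])),
                     unname(tools::md5sum(out2[[role]])))
  }

  expect_error(
    run_pipeline(run_config(), inputs[c("metabolite_panel", "resistance")],
                 file.path(dir, "run3")),
    "pathway_map")
})

test_that("run_pipeline derives resistance from clonogenic inputs and runs endpoints", {
  dir <- withr::local_tempdir()
  sim <- simulate_metabolite_panel(n_lines = 5, seed = 31)
  lines <- unique(sim$panel$cell_line)
  clono <- do.call(rbind, lapply(seq_along(lines), function(i) {
    simulate_clonogenic_assay(0.1 + 0.05 * i, 0.02, seed = 100 + i,
                              cell_line = lines[i])$assay
  }))
  g <- simulate_growth_cohort(c(control = log(3) / 8, treated = log(3) / 20),
                              n_per_arm = 4, seed = 41)
  s <- simulate_survival_cohort(n_per_group = 20, censor_day = 300, seed = 42)
  es <- simulate_survival_cohort(n_per_group = 20, censor_day = 300, seed = 43,
                                 expression = TRUE)$expression_survival
  paths <- list(metabolite_panel = file.path(dir, "panel.tsv"),
                pathway_map = file.path(dir, "map.tsv"),
                clonogenic = file.path(dir, "clono.tsv"),
                growth = file.path(dir, "growth.tsv"),
                survival = file.path(dir, "surv.tsv"),
                expression_survival = file.path(dir, "es.tsv"))
  write_table(sim$panel, paths$metabolite_panel)
  write_table(default_pathway_map(), paths$pathway_map)
  write_table(clono, paths$clonogenic)
  write_table(g$growth, paths$growth)
  write_table(s$events, paths$survival)
  write_table(es, paths$expression_survival)

  out <- run_pipeline(run_config(), paths, file.path(dir, "run"))
  fits <- read_long_table(out$lq_fits, "lq_fits")
  expect_equal(sort(fits$cell_line), sort(lines))
  expect_true(all(fits$dmid > 0))
  expect_true(file.exists(out$tripling))
  expect_true(file.exists(out$endpoint_summary))
  expect_true(file.exists(out$survival_summary))
  expect_true(file.exists(out$median_split))
})
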