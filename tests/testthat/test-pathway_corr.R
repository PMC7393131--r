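test_that("z_transform standardizes rows with sample sd and drops constants", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-1, 0, 1))
  colnames(m) <- c("L1", "L2", "L3")
  expect_warning(zm <- z_transform(m), "zero-variance")
  expect_equal(unname(zm$z["a", ]), c(-1, 0, 1))
  expect_equal(zm$dropped, "b")
  # idempotence on already-standardized rows
  z2 <- z_transform(zm$z)
  expect_equal(z2$z, zm$z, tolerance = 1e-9)
  # every retained row: mean 0, sample sd 1
  expect_true(all(abs(rowMeans(zm$z)) < 1e-9))
  expect_true(all(abs(apply(zm$z, 1, sd) - 1) < 1e-9))

  expect_error(z_transform(m[, 1:2]), "3 cell lines")
})

test_that("z_transform handles missing values pairwise-complete", {
  m <- rbind(a = c(1, 2, 3, NA), b = c(4, NA, 8, 6))
  colnames(m) <- paste0("L", 1:4)
  zm <- z_transform(m)
  expect_equal(unname(zm$n_eff), c(3, 3))
  expect_equal(unname(zm$z["a", 1:3]), c(-1, 0, 1))
  expect_true(is.na(zm$z["a", 4]))
})

test_that("regulation_calls uses strict inequalities at the thresholds", {
  z <- matrix(c(-1.5, -1.0, 0, 1.0, 1.1), nrow = 1,
              dimnames = list("m", paste0("L", 1:5)))
  calls <- regulation_calls(z)
  expect_equal(as.integer(calls), c(-1L, 0L, 0L, 0L, 1L))
  expect_true(all(regulation_calls(z, -2, 2) == 0L))
  inside <- matrix(runif(10, -0.99, 0.99), 2, 5)
  expect_true(all(regulation_calls(inside) == 0L))
  expect_error(regulation_calls(z, 1, -1), "configuration error")
})

test_that("pathway_scores computes regulated fractions per cell line", {
  calls <- matrix(c(-1L, -1L, 0L, 1L), ncol = 1,
                  dimnames = list(paste0("m", 1:4), "L1"))
  map <- data.frame(metabolite = paste0("m", 1:4), pathway = "pw")
  sc <- pathway_scores(calls, map)
  expect_equal(sc$down_score, 0.5)
  expect_equal(sc$up_score, 0.25)
  expect_equal(sc$n_measured, 4L)

  none <- matrix(0L, 3, 2, dimnames = list(paste0("m", 1:3), c("L1", "L2")))
  sc0 <- pathway_scores(none, data.frame(metabolite = paste0("m", 1:3),
                                         pathway = "pw"))
  expect_true(all(sc0$down_score == 0) && all(sc0$up_score == 0))

  single <- matrix(-1L, 1, 1, dimnames = list("m1", "L1"))
  sc1 <- pathway_scores(single, data.frame(metabolite = "m1", pathway = "pw"))
  expect_equal(sc1$down_score, 1)

  dupmap <- data.frame(metabolite = c("m1", "m1"), pathway = c("a", "b"))
  expect_error(pathway_scores(single, dupmap), "duplicate key|mapping error")
})

test_that("correlate_pathways matches the textbook Pearson + t oracle", {
  scores <- data.frame(pathway = "pw", cell_line = paste0("L", 1:5),
                       down_score = c(0.2, 0.4, 0.1, 0.5, 0.3),
                       up_score = 0, n_measured = 4L)
  resistance <- data.frame(cell_line = paste0("L", 1:5),
                           dmid = c(5, 3, 6, 2, 4))
  res <- correlate_pathways(scores, resistance, "down")
  ct <- cor.test(c(0.2, 0.4, 0.1, 0.5, 0.3), -c(5, 3, 6, 2, 4))
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-9)
  expect_equal(res$p, ct$p.value, tolerance = 1e-9)
  # this vector is exactly proportional to -dmid: perfect coupling
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)

  # zero-variance score vector: missing r, excluded from the family
  scores2 <- rbind(scores,
                   data.frame(pathway = "flat", cell_line = paste0("L", 1:5),
                              down_score = 0.2, up_score = 0, n_measured = 3L))
  res2 <- correlate_pathways(scores2, resistance, "down")
  expect_true(is.na(res2$r[res2$pathway == "flat"]))

  bad_res <- data.frame(cell_line = c("X1", "X2", "X3"), dmid = c(1, 2, 3))
  expect_error(correlate_pathways(scores, bad_res, "down"), "alignment error")
})

test_that("the scoring cascade is invariant to ordering and affine rescaling", {
  set.seed(9)
  pan <- random_small_panel(9)
  run <- function(mat) {
    zm <- suppressWarnings(z_transform(mat))
    sc <- pathway_scores(regulation_calls(zm), pan$map)
    co <- correlate_pathways(sc, pan$resistance, "down")
    co <- co[order(co$pathway), c("pathway", "r", "p", "q")]
    rownames(co) <- NULL
    co
  }
  base <- run(pan$mat)
  perm <- run(pan$mat[sample(nrow(pan$mat)), sample(ncol(pan$mat))])
  expect_equal(perm, base)

  resc <- pan$mat * runif(nrow(pan$mat), 0.5, 4) + rnorm(nrow(pan$mat))
  expect_equal(run(resc), base, tolerance = 1e-9)
})

test_that("post_rt_pathway_analysis runs the cascade on log2 fold changes", {
  # constructed 4-line panel: the 'coupled' pathway collapses post-RT in the
  # most sensitive line, driving down-calls there
  lines <- paste0("L", 1:4)
  resistance <- data.frame(cell_line = lines, dmid = c(6, 5, 2, 1))
  mets <- c(sprintf("c%d", 1:4), sprintf("u%d", 1:4))
  map <- data.frame(metabolite = mets,
                    pathway = rep(c("coupled", "other"), each = 4))
  set.seed(10)
  fcs <- lapply(seq_along(mets), function(i) {
    if (i <= 4) 2^(c(1.2, 1.0, -0.1, -1.5) + rnorm(4, sd = 0.05))
    else 2^(0.5 * c(1, -1, 1, -1) + rnorm(4, sd = 0.02))  # |z| < 1: no calls
  })
  fc_tab <- data.frame(metabolite = rep(mets, each = 4),
                       cell_line = rep(lines, length(mets)),
                       fold_change = unlist(fcs))
  out <- post_rt_pathway_analysis(fc_tab, resistance, map,
                                  config = run_config())
  co <- out$correlations
  best <- co$pathway[which.max(abs(co$r))]
  expect_equal(best, "coupled")
  # down-calls concentrate in the radiosensitive (low-Dmid) lines, so the
  # down-score rises with the sensitivity orientation (-Dmid)
  expect_gt(co$r[co$pathway == "coupled"], 0)

  # null perturbation: all fold changes 1 -> zero variance everywhere
  flat <- fc_tab; flat$fold_change <- 1
  null <- suppressWarnings(post_rt_pathway_analysis(flat, resistance, map))
  expect_null(null$correlations)
  expect_equal(nrow(null$zmatrix$z), 0)
})
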