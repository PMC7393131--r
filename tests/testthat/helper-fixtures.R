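# small in-code fixture builders shared across test files

# long metabolite panel from a named list: values[[metabolite]][[cell_line]]
# is a vector of replicate areas (single condition "basal" unless given)
make_panel <- function(values, condition = "basal") {
  rows <- list()
  for (m in names(values)) {
    for (cl in names(values[[m]])) {
      a <- values[[m]][[cl]]
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = m,
        sample = sprintf("%s_%s_r%d", cl, condition, seq_along(a)),
        cell_line = cl, condition = condition,
        replicate = seq_along(a), area = a, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

write_tmp_tsv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, paste0("tbl_", as.integer(stats::runif(1, 1, 1e8)), ".tsv"))
  radiometab::write_table(df, path)
  path
}

# clonogenic toy: one record per (dose, replicate)
make_clonogenic <- function(doses, colonies, plated, cell_line = "L1",
                            treatment = "control") {
  data.frame(cell_line = cell_line, treatment = treatment,
             dose_gy = rep(doses, each = length(colonies[[1]])),
             cells_plated = plated,
             colonies = unlist(colonies),
             replicate = rep(seq_along(colonies[[1]]), length(doses)),
             stringsAsFactors = FALSE)
}
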