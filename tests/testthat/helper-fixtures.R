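# small deterministic fixtures used across test files

# a stage series where every cell of a stage carries the stage-mean value,
# so per-stage means are exact and SDs are zero (reversal-scan fixtures)
flat_series <- function(stage_means, n_per_stage = 8) {
  genes <- rownames(stage_means)
  Tn <- ncol(stage_means)
  stage_order <- paste0("t", seq_len(Tn))
  vals <- stage_means[, rep(seq_len(Tn), each = n_per_stage), drop = FALSE]
  cells <- sprintf("c%03d", seq_len(ncol(vals)))
  colnames(vals) <- cells
  em <- expression_matrix(vals, normalized = TRUE)
  labels <- data.frame(cell_id = cells,
                       stage_label = rep(stage_order, each = n_per_stage))
  suppressMessages(assemble_stage_series(em, labels, stage_order))
}

# series from an explicit genes x cells matrix with equal stage sizes
series_from_matrix <- function(values, n_stages, normalized = TRUE) {
  n <- ncol(values) / n_stages
  stage_order <- paste0("t", seq_len(n_stages))
  labels <- data.frame(cell_id = colnames(values),
                       stage_label = rep(stage_order, each = n))
  em <- expression_matrix(values, normalized = normalized)
  suppressMessages(assemble_stage_series(em, labels, stage_order))
}

star_network <- function(center = "HUB", leaves = paste0("L", 1:4)) {
  suppressMessages(build_template_network(
    data.frame(from = center, to = leaves), c(center, leaves)))
}
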