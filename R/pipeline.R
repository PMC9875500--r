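#' Run the full SCLE pipeline and write its artifacts
#'
#' Orchestrates load -> network -> SCLE -> critical call -> DNB report ->
#' reversal scan, writing every table plus a JSON manifest that records all
#' parameters, the package version and input checksums. Identical inputs and
#' configuration produce identical outputs.
#'
#' Files written to `out_dir`: `stage_scores.tsv` (stage, H_t, R,
#' fold_change), `local_scores.tsv` (gene, stage, sd, entropy, score),
#' `dnb_genes.txt`, `dnb_neighbors.txt`, `dnb_statistics.tsv`,
#' `reversal.tsv`, `manifest.json`, and `permutation.tsv` when `B > 0`.
#'
#' @param expression_path expression matrix file.
#' @param labels_path two-column TSV (cell_id, stage_label) with header.
#' @param network_path STRING-style edge list.
#' @param stage_order character vector of stage labels in pseudotime order.
#' @param out_dir output directory, created if needed.
#' @param format expression layout, `"dense_tsv"` or `"triplet"`.
#' @param genes_path,cells_path identifier files for the triplet layout.
#' @param top_fraction fraction of network genes in the stage score.
#' @param min_cells minimum cells per stage.
#' @param score_column,min_score optional edge-confidence filter.
#' @param B permutation count for the peak null; 0 (default) skips the test.
#' @param max_pairs cap for the PCC_out pair subsample.
#' @param seed seed for permutations and subsampling.
#' @return Invisibly, a list with the fitted objects (`fit`, `report`,
#'   `reversal`, `manifest`).
#' @export
run_scle_pipeline <- function(expression_path, labels_path, network_path,
                              stage_order, out_dir,
                              format = c("dense_tsv", "triplet"),
                              genes_path = NULL, cells_path = NULL,
                              top_fraction = 0.05, min_cells = 7L,
                              score_column = NULL, min_score = NULL,
                              B = 0L, max_pairs = 1e5, seed = 1L) {
  format <- match.arg(format)
  for (p in c(expression_path, labels_path, network_path))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  step <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }

  expr_raw <- step("expression_io", load_expression(
    expression_path, format, genes_path = genes_path, cells_path = cells_path))
  expr_norm <- step("expression_io", normalize_log1p(expr_raw))
  labels <- step("expression_io", utils::read.table(
    labels_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  series <- step("expression_io", assemble_stage_series(
    expr_norm, labels, stage_order, min_cells = min_cells))
  edges <- step("network", load_edge_list(
    network_path, score_column = score_column, min_score = min_score))
  network <- step("network", build_template_network(
    edges, rownames(series$matrix$values)))
  fit <- step("scle_core", scle(series, network, top_fraction = top_fraction))
  report <- step("dnb_report", dnb_report(
    fit, series, network, max_pairs = max_pairs, seed = seed))
  rev_tab <- step("reversal", reversal_scan(
    series, report$neighbors, fit$critical_stage))

  perm <- NULL
  if (B > 0L)
    perm <- step("scle_core", scle_permutation_test(
      fit, series, network, B = B, seed = seed))

  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  stage_tab <- data.frame(stage = names(fit$stage_scores),
                          H_t = unname(fit$stage_scores), R = fit$R,
                          fold_change = NA_real_)
  crit_i <- match(fit$critical_stage, stage_tab$stage)
  stage_tab$fold_change[crit_i] <- fit$fold_change
  wt(stage_tab, "stage_scores.tsv")
  wt(fit$local_scores, "local_scores.tsv")
  writeLines(report$dnb_genes, file.path(out_dir, "dnb_genes.txt"))
  writeLines(report$neighbors, file.path(out_dir, "dnb_neighbors.txt"))
  wt(report$statistics, "dnb_statistics.tsv")
  wt(rev_tab, "reversal.tsv")
  if (!is.null(perm))
    wt(data.frame(p_value = perm$p.value, B = perm$B,
                  observed_peak = perm$observed), "permutation.tsv")

  manifest <- list(
    package = "scle",
    version = as.character(utils::packageVersion("scle")),
    parameters = list(stage_order = stage_order, format = format,
                      top_fraction = top_fraction,
                      min_cells = as.integer(min_cells),
                      score_column = score_column, min_score = min_score,
                      B = as.integer(B), max_pairs = max_pairs,
                      seed = as.integer(seed)),
    conventions = list(log_base = "natural", sd = "sample (n-1)",
                       q1_entropy = 1, constant_vector_pcc = 0),
    inputs = list(
      expression = list(path = expression_path,
                        md5 = unname(tools::md5sum(expression_path))),
      labels = list(path = labels_path,
                    md5 = unname(tools::md5sum(labels_path))),
      network = list(path = network_path,
                     md5 = unname(tools::md5sum(network_path))),
      genes = if (is.null(genes_path)) NULL else
        list(path = genes_path, md5 = unname(tools::md5sum(genes_path))),
      cells = if (is.null(cells_path)) NULL else
        list(path = cells_path, md5 = unname(tools::md5sum(cells_path)))),
    results = list(critical_stage = fit$critical_stage,
                   fold_change = fit$fold_change,
                   end_of_series_warning = fit$end_of_series_warning,
                   R = fit$R, M = fit$M,
                   p_value = if (is.null(perm)) NULL else perm$p.value))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(fit = fit, report = report, reversal = rev_tab,
                 permutation = perm, manifest = manifest,
                 series = series, network = network))
}

#' Re-run a pipeline from its manifest
#'
#' Reads a `manifest.json` written by [run_scle_pipeline()] and replays the
#' run with the recorded parameters and inputs, so any result can be
#' regenerated bit-identically from the manifest alone.
#'
#' @param manifest_path path to a `manifest.json`.
#' @param out_dir output directory for the replay.
#' @return As [run_scle_pipeline()].
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  p <- m$parameters
  run_scle_pipeline(
    expression_path = m$inputs$expression$path,
    labels_path = m$inputs$labels$path,
    network_path = m$inputs$network$path,
    stage_order = p$stage_order, out_dir = out_dir,
    format = p$format,
    genes_path = m$inputs$genes$path, cells_path = m$inputs$cells$path,
    top_fraction = p$top_fraction, min_cells = p$min_cells,
    score_column = p$score_column, min_score = p$min_score,
    B = p$B, max_pairs = p$max_pairs, seed = p$seed)
}

#' Write a simulated data set in the pipeline's input formats
#'
#' Materializes a [simulate_transition()] draw as the four on-disk artifacts
#' the pipeline consumes (dense expression TSV, label TSV, edge list,
#' stage-order file) plus a ground-truth JSON.
#'
#' @param sim result of [simulate_transition()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             network = file.path(dir, "network.tsv"),
             stage_order = file.path(dir, "stage_order.txt"),
             truth = file.path(dir, "truth.json"))
  v <- sim$expression$values
  tab <- data.frame(gene = rownames(v), v, check.names = FALSE)
  utils::write.table(tab, paths[["expression"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$labels, paths[["labels"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  et <- edge_table(sim$network)
  colnames(et) <- c("protein1", "protein2")
  utils::write.table(et, paths[["network"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sim$stage_order, paths[["stage_order"]])
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}
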