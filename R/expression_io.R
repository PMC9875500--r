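#' Construct an expression matrix container
#'
#' Wraps a gene-by-cell matrix of non-negative expression values together
#' with a flag recording whether the values have been log-normalized.
#' Gene symbols are rows, cell identifiers are columns; both must be unique.
#'
#' @param values numeric matrix, genes in rows, cells in columns, with
#'   complete `dimnames`.
#' @param normalized logical; `TRUE` once values are on the `ln(1 + x)` scale.
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values` (the matrix) and `normalized`.
#' @export
expression_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  genes <- rownames(values)
  cells <- colnames(values)
  if (is.null(genes) || is.null(cells))
    stop("`values` must carry gene rownames and cell colnames", call. = FALSE)
  dup_g <- genes[duplicated(genes)]
  if (length(dup_g))
    stop("duplicate gene symbol(s): ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  dup_c <- cells[duplicated(cells)]
  if (length(dup_c))
    stop("duplicate cell identifier(s): ", paste(unique(dup_c), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(values) | (!normalized & values < 0), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-finite or negative value at gene '%s', cell '%s'",
                 genes[bad[1L, 1L]], cells[bad[1L, 2L]]), call. = FALSE)
  }
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "expression_matrix")
}

#' @method print expression_matrix
#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "log-normalized" else "raw"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported. `"dense_tsv"` is a tab-separated table
#' whose first column holds gene symbols and whose header row holds cell
#' identifiers. `"triplet"` is MatrixMarket coordinate format accompanied by
#' one-column gene and cell identifier files (row order of those files fixes
#' the matrix row/column order); coordinates absent from the file are zero.
#'
#' @param path path to the matrix file.
#' @param format `"dense_tsv"` or `"triplet"`.
#' @param genes_path,cells_path identifier files, required for `"triplet"`.
#' @return An [expression_matrix()] with `normalized = FALSE`.
#' @export
load_expression <- function(path, format = c("dense_tsv", "triplet"),
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  if (format == "dense_tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = NA,
                             stringsAsFactors = FALSE, comment.char = "")
    genes <- trimws(as.character(tab[[1L]]))
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(vals)) {
      idx <- which(is.na(suppressWarnings(apply(vals, 2L, as.numeric))),
                   arr.ind = TRUE)
      stop(sprintf("non-numeric value near row %d, column %d of %s",
                   idx[1L, 1L], idx[1L, 2L] + 1L, path), call. = FALSE)
    }
    rownames(vals) <- genes
    colnames(vals) <- trimws(colnames(vals))
  } else {
    if (is.null(genes_path) || is.null(cells_path))
      stop("triplet format requires `genes_path` and `cells_path`", call. = FALSE)
    mm <- Matrix::readMM(path)
    genes <- trimws(readLines(genes_path))
    cells <- trimws(readLines(cells_path))
    if (nrow(mm) != length(genes) || ncol(mm) != length(cells))
      stop(sprintf("matrix is %d x %d but %d genes / %d cells listed",
                   nrow(mm), ncol(mm), length(genes), length(cells)),
           call. = FALSE)
    vals <- as.matrix(mm)
    dimnames(vals) <- list(genes, cells)
  }
  expression_matrix(vals, normalized = FALSE)
}

#' Log-normalize an expression matrix
#'
#' Applies the elementwise transform `x -> ln(1 + x)`. The natural logarithm
#' is used throughout the package; the downstream entropy score is invariant
#' to the base, so one consistent choice suffices.
#'
#' @param x an [expression_matrix()] with `normalized = FALSE`.
#' @return The matrix with every value replaced by `ln(1 + x)` and
#'   `normalized = TRUE`.
#' @export
normalize_log1p <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$normalized)
    stop("matrix is already normalized (double-normalization guard)",
         call. = FALSE)
  out <- x
  out$values <- log1p(x$values)
  out$normalized <- TRUE
  out
}

#' Assemble a staged expression series
#'
#' Attaches an ordered cell-to-stage partition to a normalized expression
#' matrix. Stages play the role of ordered pseudotime clusters: stage t = 1
#' is the first element of `stage_order` and so on. Cells present in the
#' matrix but missing from the label table are dropped (stage labels
#' typically cover only the trajectory subset of the cells); the count of
#' dropped cells is reported via `message()`.
#'
#' @param x a normalized [expression_matrix()].
#' @param labels data.frame with columns `cell_id` and `stage_label` (or any
#'   two columns in that order).
#' @param stage_order character vector of the T distinct stage labels in
#'   pseudotime order.
#' @param min_cells minimum cells per stage; default 7, i.e. strictly more
#'   than 6 cells are required for the stage-wise moments to be stable.
#' @return An object of class `"stage_series"`: list with `matrix`
#'   (the expression_matrix restricted to labelled cells), `stages` (named
#'   factor cell -> stage with levels `stage_order`) and `stage_order`.
#' @export
assemble_stage_series <- function(x, labels, stage_order, min_cells = 7L) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!x$normalized)
    stop("expression matrix must be normalized before staging", call. = FALSE)
  if (length(stage_order) < 2L || anyDuplicated(stage_order))
    stop("`stage_order` must list at least two distinct stages", call. = FALSE)
  labels <- as.data.frame(labels)
  if (ncol(labels) < 2L) stop("label table needs cell and stage columns", call. = FALSE)
  cell_id <- trimws(as.character(labels[[1L]]))
  stage_label <- trimws(as.character(labels[[2L]]))
  if (anyDuplicated(cell_id))
    stop("duplicate cell in label table: ",
         cell_id[duplicated(cell_id)][1L], call. = FALSE)
  unknown <- setdiff(unique(stage_label), stage_order)
  if (length(unknown))
    stop("stage label(s) not in stage_order: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  cells <- colnames(x$values)
  keep <- intersect(cells, cell_id)
  dropped <- length(cells) - length(keep)
  if (dropped > 0L)
    message(sprintf("assemble_stage_series: dropped %d unlabelled cell(s)", dropped))
  if (!length(keep)) stop("no labelled cells found in the matrix", call. = FALSE)

  stages <- factor(stage_label[match(keep, cell_id)], levels = stage_order)
  names(stages) <- keep
  counts <- table(stages)
  short <- names(counts)[counts < min_cells]
  if (length(short))
    stop(sprintf("stage '%s' has %d cells; at least %d required",
                 short[1L], counts[[short[1L]]], min_cells), call. = FALSE)

  out <- x
  out$values <- x$values[, keep, drop = FALSE]
  structure(list(matrix = out, stages = stages,
                 stage_order = as.character(stage_order)),
            class = "stage_series")
}

#' @method print stage_series
#' @export
print.stage_series <- function(x, ...) {
  counts <- table(x$stages)
  cat(sprintf("stage_series: %d genes, %d cells, %d stages\n",
              nrow(x$matrix$values), ncol(x$matrix$values),
              length(x$stage_order)))
  cat("  cells per stage:",
      paste(sprintf("%s=%d", names(counts), as.integer(counts)),
            collapse = ", "), "\n")
  invisible(x)
}

# columns of the expression matrix belonging to one stage
stage_values <- function(series, stage, genes = NULL) {
  cells <- names(series$stages)[series$stages == stage]
  v <- series$matrix$values[, cells, drop = FALSE]
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  v
}
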