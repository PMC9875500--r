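#' Scan genes for expression reversal across the critical stage
#'
#' DNB-neighbouring genes often flip the sign of their expression trend
#' after the critical period ("flip-flop"). This scan quantifies the flip
#' with a two-slope statistic: per gene, the least-squares slope of the
#' per-stage mean expression against the stage index is fitted over the
#' stages up to and including the critical stage, and again from the
#' critical stage to the end (the critical stage belongs to both windows so
#' each has at least two points whenever the critical stage is interior).
#' The reversal score is `-(slope_before * slope_after)`: positive when the
#' trend changes sign. A gene is flagged `reversed` when the score is
#' positive and both slopes clear `epsilon` in magnitude.
#'
#' When the critical stage is the first or last stage no reversal call is
#' possible; all genes are returned unflagged with an explanatory message.
#'
#' @param series a [assemble_stage_series()] object.
#' @param genes character vector of measured genes to scan (typically the
#'   DNB neighbours).
#' @param critical_stage stage label, usually from a fitted [scle()] object.
#' @param epsilon slope magnitude below which a trend counts as flat;
#'   default 1e-6 on the log-expression scale.
#' @return data.frame, one row per gene, sorted by `reversal_score`
#'   descending: gene, one `mean_<stage>` column per stage, `slope_before`,
#'   `slope_after`, `reversal_score`, `reversed`.
#' @export
reversal_scan <- function(series, genes, critical_stage, epsilon = 1e-6) {
  stopifnot(inherits(series, "stage_series"))
  missing <- setdiff(genes, rownames(series$matrix$values))
  if (length(missing))
    stop("gene(s) not measured: ", paste(missing, collapse = ", "), call. = FALSE)
  ord <- series$stage_order
  t_star <- match(critical_stage, ord)
  if (is.na(t_star)) stop("unknown critical stage: ", critical_stage, call. = FALSE)
  T <- length(ord)

  means <- vapply(ord, function(st)
    rowMeans(stage_values(series, st, genes)), numeric(length(genes)))
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, paste0("mean_", ord)))

  interior <- t_star >= 2L && t_star <= T - 1L
  if (!interior)
    message("reversal_scan: critical stage at the series boundary; no reversal calls made")

  ls_slope <- function(y, idx) {
    if (length(idx) < 2L) return(NA_real_)
    stats::cov(idx, y[idx]) / stats::var(idx)
  }
  before_idx <- seq_len(t_star)
  after_idx <- t_star:T
  slope_before <- apply(means, 1L, ls_slope, idx = before_idx)
  slope_after <- apply(means, 1L, ls_slope, idx = after_idx)
  score <- -(slope_before * slope_after)
  reversed <- interior & !is.na(score) & score > 0 &
    abs(slope_before) > epsilon & abs(slope_after) > epsilon

  out <- data.frame(gene = genes, means, slope_before = slope_before,
                    slope_after = slope_after,
                    reversal_score = ifelse(is.na(score), 0, score),
                    reversed = reversed, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$reversal_score, out$gene), , drop = FALSE]
}
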