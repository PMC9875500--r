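#' Absolute Pearson correlation with the constant-vector convention
#'
#' Returns `|PCC(x, y)|`, and 0 when either vector has zero variance: a gene
#' that does not vary within a stage carries no detectable coordination with
#' its neighbours, so its correlation weight is defined as zero rather than
#' left undefined.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return A number in `[0, 1]`.
#' @export
pearson_abs <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  abs(stats::cor(x, y))
}

# Precomputed edge index structure for fast repeated scoring: endpoints of
# every undirected edge as integer indices into the gene order, plus
# degrees. Correlations are evaluated edge-wise (O(E * cells)), never as a
# dense gene x gene matrix, so large PPI graphs stay tractable.
make_score_ctx <- function(network, genes) {
  el <- igraph::as_edgelist(network$graph)
  ei <- match(el[, 1L], genes)
  ej <- match(el[, 2L], genes)
  M <- length(genes)
  list(genes = genes, M = M, ei = ei, ej = ej,
       degree = tabulate(c(ei, ej), M))
}

# per-gene sd, entropy and score for one stage, fully vectorized.
# values: genes x cells in ctx$genes order.
stage_score_parts <- function(values, ctx) {
  n <- ncol(values)
  xc <- values - rowMeans(values)
  ss <- rowSums(xc^2)
  sds <- sqrt(ss / (n - 1))
  z <- xc / sqrt(ifelse(ss > 0, ss, 1))
  z[ss == 0, ] <- 0                 # constant gene: |PCC| = 0 by convention
  w <- abs(rowSums(z[ctx$ei, , drop = FALSE] * z[ctx$ej, , drop = FALSE]))
  w <- pmin(w, 1)
  wl <- ifelse(w > 0, w * log(w), 0)
  agg <- rowsum(cbind(c(w, w), c(wl, wl)), c(ctx$ei, ctx$ej))
  S <- numeric(ctx$M)
  T1 <- numeric(ctx$M)
  gi <- as.integer(rownames(agg))
  S[gi] <- agg[, 1L]
  T1[gi] <- agg[, 2L]               # sum_j w_j log w_j
  # sum_i p_i log p_i = T1/S - log(S) with p_i = w_i / S
  entropy <- numeric(ctx$M)
  pos <- S > 0
  multi <- pos & ctx$degree >= 2L
  entropy[multi] <- -(T1[multi] / S[multi] - log(S[multi])) / log(ctx$degree[multi])
  entropy[pos & ctx$degree == 1L] <- 1  # one-neighbour limit of the uniform law
  list(sd = sds, entropy = entropy, score = entropy * sds)
}

stage_local_scores <- function(values, ctx) {
  p <- stage_score_parts(values, ctx)
  data.frame(gene = ctx$genes, sd = unname(p$sd),
             entropy = p$entropy, score = unname(p$score),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Local SCLE score of one gene at one stage
#'
#' The local score of a gene g at stage t is the normalized Shannon entropy
#' of its neighbour-correlation weights multiplied by its standard deviation:
#' \deqn{H_t^{(k)} = \Big[-\frac{1}{\ln Q}\sum_{i=1}^{Q} p_i(t)\ln p_i(t)\Big]
#'   \times SD(g^k(t)),}
#' where the weights \eqn{p_i(t)} are the absolute Pearson correlations of g
#' with each of its Q first-order neighbours, normalized to sum to one. The
#' standard deviation is the sample SD (divisor n - 1) across the stage's
#' cells. Conventions for degenerate cases: entropy is 1 when Q = 1 (uniform
#' law on a single outcome), 0 when every neighbour correlation is 0, and
#' terms with \eqn{p_i = 0} contribute 0.
#'
#' @param series a [assemble_stage_series()] object.
#' @param ln a [local_network()] object.
#' @param stage stage label.
#' @return List with `gene`, `stage`, `sd`, `weights` (normalized, or NULL
#'   when all raw weights vanish), `entropy` and `score`.
#' @export
local_scle <- function(series, ln, stage) {
  stopifnot(inherits(series, "stage_series"), inherits(ln, "local_network"))
  if (!stage %in% series$stage_order)
    stop("unknown stage: ", stage, call. = FALSE)
  genes <- c(ln$center, ln$neighbors)
  missing <- setdiff(genes, rownames(series$matrix$values))
  if (length(missing))
    stop("gene(s) not measured: ", paste(missing, collapse = ", "), call. = FALSE)
  v <- stage_values(series, stage, genes)
  center <- v[1L, ]
  sd_c <- stats::sd(center)
  w <- vapply(seq_len(ln$Q), function(i) pearson_abs(center, v[i + 1L, ]),
              numeric(1))
  sw <- sum(w)
  if (sw == 0) {
    entropy <- 0
    p <- NULL
  } else if (ln$Q == 1L) {
    entropy <- 1
    p <- 1
  } else {
    p <- w / sw
    plp <- ifelse(p > 0, p * log(p), 0)
    entropy <- -sum(plp) / log(ln$Q)
  }
  list(gene = ln$center, stage = stage, sd = sd_c, weights = p,
       entropy = entropy, score = entropy * sd_c)
}

#' Fit the stage-wise single-cell landscape entropy profile
#'
#' For every gene of the template network and every stage, computes the local
#' SCLE score (see [local_scle()]); the stage score \eqn{H_t} is the sum of
#' the R largest local scores at that stage, with
#' \eqn{R = \lceil \mathrm{top\_fraction} \times M \rceil} and M the number
#' of network genes. A sharp rise of \eqn{H_t} marks the critical
#' (pre-deteriorated) stage, which is called as the argmax of the profile.
#'
#' Ranking ties are broken lexicographically by gene symbol so repeated runs
#' are bit-reproducible.
#'
#' @param series a [assemble_stage_series()] object.
#' @param network a [build_template_network()] object; its nodes must all be
#'   measured in `series`.
#' @param top_fraction fraction of network genes summed into the stage
#'   score; default 0.05 (the top 5 percent).
#' @return An object of class `"scle"` with components `local_scores`
#'   (data.frame gene/stage/sd/entropy/score), `stage_scores` (named numeric
#'   \eqn{H_t}), `R`, `top_genes` (per-stage character vectors of the R
#'   contributing genes), `critical_stage`, `fold_change`,
#'   `end_of_series_warning` and `stage_order`.
#' @seealso [detect_critical_stage()], [scle_permutation_test()],
#'   [dnb_report()]
#' @export
scle <- function(series, network, top_fraction = 0.05) {
  stopifnot(inherits(series, "stage_series"),
            inherits(network, "template_network"))
  if (!(top_fraction > 0 && top_fraction <= 1))
    stop("`top_fraction` must lie in (0, 1]", call. = FALSE)
  genes <- network$nodes
  missing <- setdiff(genes, rownames(series$matrix$values))
  if (length(missing))
    stop("network gene(s) not measured: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  M <- length(genes)
  R <- max(1L, as.integer(ceiling(top_fraction * M)))

  ctx <- make_score_ctx(network, genes)

  per_stage <- lapply(series$stage_order, function(st) {
    sc <- stage_local_scores(stage_values(series, st, genes), ctx)
    sc$stage <- st
    sc
  })
  local_scores <- do.call(rbind, per_stage)
  local_scores <- local_scores[, c("gene", "stage", "sd", "entropy", "score")]

  top_genes <- list()
  H <- numeric(length(series$stage_order))
  names(H) <- series$stage_order
  for (i in seq_along(per_stage)) {
    sc <- per_stage[[i]]
    ord <- order(-sc$score, sc$gene)
    top <- ord[seq_len(R)]
    H[i] <- sum(sc$score[top])
    top_genes[[series$stage_order[i]]] <- sc$gene[top]
  }

  fit <- structure(list(local_scores = local_scores, stage_scores = H,
                        R = R, top_fraction = top_fraction,
                        top_genes = top_genes,
                        stage_order = series$stage_order,
                        M = M, call = match.call()),
                   class = "scle")
  crit <- detect_critical_stage(fit)
  fit$critical_stage <- crit$critical_stage
  fit$fold_change <- crit$fold_change
  fit$end_of_series_warning <- crit$end_of_series_warning
  fit
}

#' Call the critical stage from a fitted SCLE profile
#'
#' The critical stage is the argmax of the stage score \eqn{H_t} (earliest
#' stage on ties). The fold change relative to the preceding stage is
#' reported alongside (`Inf` when the peak is the first stage or the
#' preceding score is 0). When the argmax falls on the final stage the call
#' is flagged: a peak cannot then be distinguished from a monotone rise.
#'
#' @param fit an object of class `"scle"`, or a named numeric vector of
#'   stage scores in stage order.
#' @return List with `critical_stage`, `fold_change` and
#'   `end_of_series_warning`.
#' @export
detect_critical_stage <- function(fit) {
  H <- if (inherits(fit, "scle")) fit$stage_scores else fit
  if (length(H) < 2L) stop("need at least two stages", call. = FALSE)
  i <- which.max(H)  # which.max returns the earliest maximum
  fold <- if (i == 1L || H[i - 1L] == 0) Inf else unname(H[i] / H[i - 1L])
  list(critical_stage = names(H)[i], fold_change = fold,
       end_of_series_warning = (i == length(H)))
}

#' Permutation null for the peak SCLE score
#'
#' Permutes the cell-to-stage assignment (preserving stage sizes) B times,
#' recomputes the maximal stage score \eqn{\max_t H_t} under each
#' permutation, and reports
#' \eqn{p = (1 + \#\{\max^{perm} \ge \max^{obs}\}) / (B + 1)}. Under the
#' null of exchangeable cells there is no stage-specific coordination, so an
#' observed peak comparable to the permuted peaks is unremarkable.
#'
#' @param fit a fitted [scle()] object.
#' @param series,network the inputs the fit was computed from.
#' @param B number of permutations (at least 1).
#' @param seed integer seed; fixed seed gives a reproducible p-value.
#' @return List with `p.value`, `B`, `observed` and `perm_max` (length-B
#'   vector of permuted peak scores).
#' @export
scle_permutation_test <- function(fit, series, network, B = 99L, seed = 1L) {
  stopifnot(inherits(fit, "scle"))
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  genes <- network$nodes
  ctx <- make_score_ctx(network, genes)
  vals <- series$matrix$values[genes, , drop = FALSE]
  stages <- series$stages[colnames(vals)]
  R <- fit$R
  observed <- max(fit$stage_scores)

  peak_of <- function(stage_vec) {
    max(vapply(series$stage_order, function(st) {
      p <- stage_score_parts(vals[, stage_vec == st, drop = FALSE], ctx)
      sum(sort(p$score, decreasing = TRUE)[seq_len(R)])
    }, numeric(1)))
  }

  old <- .Random.seed_exists()
  set.seed(seed)
  perm_max <- vapply(seq_len(B), function(b) {
    peak_of(sample(stages))
  }, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  p <- (1 + sum(perm_max >= observed)) / (B + 1)
  list(p.value = p, B = B, observed = observed, perm_max = perm_max)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

#' @method print scle
#' @export
print.scle <- function(x, ...) {
  cat("Single-cell landscape entropy profile\n")
  cat(sprintf("  %d network genes, %d stages, R = %d (top %.1f%%)\n",
              x$M, length(x$stage_order), x$R, 100 * x$top_fraction))
  cat("  stage scores H_t:\n")
  print(round(x$stage_scores, 4))
  cat(sprintf("  critical stage: %s (fold change %.3g%s)\n",
              x$critical_stage, x$fold_change,
              if (x$end_of_series_warning)
                "; peak at final stage - monotone rise not excluded" else ""))
  invisible(x)
}

#' @export
coef.scle <- function(object, ...) object$stage_scores

#' @method summary scle
#' @export
summary.scle <- function(object, ...) {
  ls <- object$local_scores
  crit <- ls[ls$stage == object$critical_stage, ]
  crit <- crit[order(-crit$score, crit$gene), ]
  structure(list(stage_scores = object$stage_scores,
                 critical_stage = object$critical_stage,
                 fold_change = object$fold_change,
                 end_of_series_warning = object$end_of_series_warning,
                 R = object$R, M = object$M,
                 top_fraction = object$top_fraction,
                 top_at_critical = utils::head(crit, 10L)),
            class = "summary.scle")
}

#' @method print summary.scle
#' @export
print.summary.scle <- function(x, ...) {
  cat("SCLE profile summary\n\n")
  cat(sprintf("Network genes M = %d; R = %d (top fraction %.3f)\n",
              x$M, x$R, x$top_fraction))
  cat("\nStage scores:\n")
  print(round(x$stage_scores, 4))
  cat(sprintf("\nCritical stage: %s, fold change %.3g\n",
              x$critical_stage, x$fold_change))
  if (x$end_of_series_warning)
    cat("Note: peak at the final stage; a monotone rise cannot be excluded.\n")
  cat("\nTop local scores at the critical stage:\n")
  print(x$top_at_critical, row.names = FALSE)
  invisible(x)
}

#' Plot the stage SCLE profile
#'
#' Draws \eqn{H_t} against the stage index and marks the called critical
#' stage.
#'
#' @param x an object of class `"scle"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scle <- function(x, ...) {
  H <- x$stage_scores
  idx <- seq_along(H)
  graphics::plot(idx, H, type = "b", pch = 19, xaxt = "n",
                 xlab = "stage", ylab = expression(H[t]), ...)
  graphics::axis(1, at = idx, labels = names(H))
  ci <- match(x$critical_stage, names(H))
  graphics::points(ci, H[ci], col = "red", pch = 19, cex = 1.5)
  graphics::abline(v = ci, lty = 3, col = "red")
  invisible(x)
}
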