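#' Extract the DNB gene module at the critical stage
#'
#' The dynamic-network-biomarker (DNB) genes are the R genes whose local
#' SCLE scores compose the stage score at the called critical stage, i.e.
#' the top-R genes by local score there (lexicographic tie-break).
#'
#' @param fit a fitted [scle()] object.
#' @return Character vector of R gene symbols, in rank order.
#' @export
identify_dnb_genes <- function(fit) {
  stopifnot(inherits(fit, "scle"))
  if (is.null(fit$critical_stage)) stop("critical stage not called", call. = FALSE)
  fit$top_genes[[fit$critical_stage]]
}

#' First-order network neighbours of the DNB module
#'
#' @param network a [build_template_network()] object.
#' @param dnb_genes character vector of DNB genes, all network nodes.
#' @return Sorted character vector: the union of first-order neighbours of
#'   the DNB genes, minus the DNB genes themselves.
#' @export
find_dnb_neighbors <- function(network, dnb_genes) {
  stopifnot(inherits(network, "template_network"))
  absent <- setdiff(dnb_genes, network$nodes)
  if (length(absent))
    stop("DNB gene(s) absent from the network: ",
         paste(absent, collapse = ", "), call. = FALSE)
  nb <- unique(unlist(lapply(dnb_genes, function(g)
    igraph::neighbors(network$graph, g)$name)))
  sort(setdiff(nb, dnb_genes))
}

#' The three DNB-property statistics at one stage
#'
#' Computes, over the cells of one stage, the three group statistics whose
#' joint behaviour signals an impending critical transition: `SD_in`, the
#' mean per-gene standard deviation inside the DNB group (rises sharply at
#' the critical stage); `PCC_in`, the mean absolute Pearson correlation over
#' all unordered DNB gene pairs (rises sharply); and `PCC_out`, the mean
#' absolute correlation over DNB x non-DNB pairs (falls). When the number of
#' cross pairs exceeds `max_pairs` a seeded uniform subsample without
#' replacement is used.
#'
#' @param series a [assemble_stage_series()] object.
#' @param dnb_genes,non_dnb_genes disjoint measured gene sets.
#' @param stage stage label.
#' @param max_pairs cap on the number of DNB x non-DNB pairs evaluated;
#'   default 1e5.
#' @param seed seed for the pair subsample.
#' @return Named numeric vector `c(SD_in, PCC_in, PCC_out)`. With a single
#'   DNB gene `PCC_in` is `NA` (no pairs) and a warning is raised.
#' @export
dnb_statistics <- function(series, dnb_genes, non_dnb_genes, stage,
                           max_pairs = 1e5, seed = 1L) {
  stopifnot(inherits(series, "stage_series"))
  if (!length(dnb_genes)) stop("empty DNB gene set", call. = FALSE)
  genes <- c(dnb_genes, non_dnb_genes)
  missing <- setdiff(genes, rownames(series$matrix$values))
  if (length(missing))
    stop("gene(s) not measured: ", paste(missing, collapse = ", "), call. = FALSE)

  vin <- stage_values(series, stage, dnb_genes)
  sd_in <- mean(apply(vin, 1L, stats::sd))

  if (length(dnb_genes) >= 2L) {
    Cin <- suppressWarnings(abs(stats::cor(t(vin))))
    Cin[!is.finite(Cin)] <- 0
    pcc_in <- mean(Cin[upper.tri(Cin)])
  } else {
    warning("single DNB gene: PCC_in undefined")
    pcc_in <- NA_real_
  }

  if (length(non_dnb_genes)) {
    n_pairs <- length(dnb_genes) * length(non_dnb_genes)
    vout <- stage_values(series, stage, non_dnb_genes)
    Cx <- suppressWarnings(abs(stats::cor(t(vin), t(vout))))
    Cx[!is.finite(Cx)] <- 0
    if (n_pairs > max_pairs) {
      old <- .Random.seed_exists()
      set.seed(seed)
      idx <- sample.int(n_pairs, max_pairs)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      pcc_out <- mean(Cx[idx])
    } else {
      pcc_out <- mean(Cx)
    }
  } else {
    pcc_out <- NA_real_
  }
  c(SD_in = sd_in, PCC_in = pcc_in, PCC_out = pcc_out)
}

#' DNB report: module, neighbours and per-stage property curves
#'
#' Bundles the DNB module extracted from a fitted profile, its first-order
#' network neighbours, and the three property statistics evaluated at every
#' stage, so the before / critical / after signature can be inspected
#' directly.
#'
#' @inheritParams dnb_statistics
#' @param fit a fitted [scle()] object.
#' @param network the template network the fit used.
#' @return An object of class `"dnb_report"`: list with `dnb_genes`,
#'   `neighbors`, `critical_stage` and `statistics` (data.frame with one row
#'   per stage: stage, SD_in, PCC_in, PCC_out).
#' @export
dnb_report <- function(fit, series, network, max_pairs = 1e5, seed = 1L) {
  stopifnot(inherits(fit, "scle"))
  dnb <- identify_dnb_genes(fit)
  non_dnb <- setdiff(network$nodes, dnb)
  stats_tab <- do.call(rbind, lapply(series$stage_order, function(st) {
    s <- dnb_statistics(series, dnb, non_dnb, st,
                        max_pairs = max_pairs, seed = seed)
    data.frame(stage = st, SD_in = s[["SD_in"]], PCC_in = s[["PCC_in"]],
               PCC_out = s[["PCC_out"]], stringsAsFactors = FALSE)
  }))
  structure(list(dnb_genes = sort(dnb),
                 neighbors = find_dnb_neighbors(network, dnb),
                 critical_stage = fit$critical_stage,
                 statistics = stats_tab),
            class = "dnb_report")
}

#' @method print dnb_report
#' @export
print.dnb_report <- function(x, ...) {
  cat(sprintf("DNB report: %d module genes, %d neighbouring genes, critical stage %s\n",
              length(x$dnb_genes), length(x$neighbors), x$critical_stage))
  cat("per-stage statistics:\n")
  print(transform(x$statistics,
                  SD_in = round(SD_in, 4), PCC_in = round(PCC_in, 4),
                  PCC_out = round(PCC_out, 4)), row.names = FALSE)
  invisible(x)
}
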