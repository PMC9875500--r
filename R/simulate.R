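#' Configuration for the planted-transition simulator
#'
#' Collects and validates the generation parameters for
#' [simulate_transition()]. The defaults encode the canonical DNB signature:
#' a connected 20-gene module inside a 200-gene network whose within-module
#' standard deviation triples, within-module correlation jumps to 0.8 and
#' module-to-outside correlation is damped to a quarter of baseline at the
#' fourth of six stages.
#'
#' @param M number of genes.
#' @param T_stages number of ordered stages.
#' @param n_per_stage cells per stage (at least 7).
#' @param module_size planted DNB module size m (connected subgraph).
#' @param critical_stage index t* (1..T) of the planted critical stage.
#' @param sigma0 baseline per-gene SD on the log scale.
#' @param sigma_ratio module SD inflation at t* (sigma1 = sigma_ratio * sigma0).
#' @param rho_base baseline correlation planted on network edges.
#' @param rho_in within-module pairwise correlation at t*.
#' @param rho_out_factor damping of the module-to-outside edge correlation
#'   at t* (edge correlation becomes rho_base * rho_out_factor).
#' @param network_model `"erdos_renyi"` or `"barabasi_albert"`.
#' @param p Erdos-Renyi edge probability.
#' @param ba_m edges attached per new node in the Barabasi-Albert model.
#' @param mu0 baseline latent mean on the log scale; large enough that
#'   truncation at zero is rare (mu0 / (sigma_ratio * sigma0) > 3).
#' @param neighbor_reversal add a deterministic rise-then-fall mean profile
#'   (peak at t*) to one non-module neighbour gene.
#' @param reversal_amplitude peak height of that profile, log-scale units.
#' @param count_layer draw Poisson counts of the exponentiated latent values
#'   instead of returning the deterministic transform (off by default).
#' @param seed integer seed; the whole draw is reproducible from it.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(M = 200L, T_stages = 6L, n_per_stage = 60L,
                              module_size = 20L, critical_stage = 4L,
                              sigma0 = 0.5, sigma_ratio = 3,
                              rho_base = 0.1, rho_in = 0.8,
                              rho_out_factor = 0.25,
                              network_model = c("erdos_renyi", "barabasi_albert"),
                              p = 0.04, ba_m = 3L, mu0 = 5,
                              neighbor_reversal = FALSE,
                              reversal_amplitude = 2,
                              count_layer = FALSE, seed = 1L) {
  network_model <- match.arg(network_model)
  stopifnot(module_size < M, critical_stage >= 1L,
            critical_stage <= T_stages, T_stages >= 2L,
            rho_base >= 0, rho_base <= rho_in, rho_in < 1,
            sigma_ratio >= 1, n_per_stage >= 7L, sigma0 > 0,
            rho_out_factor >= 0, rho_out_factor <= 1)
  structure(list(M = as.integer(M), T_stages = as.integer(T_stages),
                 n_per_stage = as.integer(n_per_stage),
                 module_size = as.integer(module_size),
                 critical_stage = as.integer(critical_stage),
                 sigma0 = sigma0, sigma_ratio = sigma_ratio,
                 rho_base = rho_base, rho_in = rho_in,
                 rho_out_factor = rho_out_factor,
                 network_model = network_model, p = p,
                 ba_m = as.integer(ba_m), mu0 = mu0,
                 neighbor_reversal = isTRUE(neighbor_reversal),
                 reversal_amplitude = reversal_amplitude,
                 count_layer = isTRUE(count_layer),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# eigenvalue clipping at `floor`; deterministic nearest-PD repair
nearest_pd <- function(S, floor = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= floor)) return(S)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

# connected m-subgraph by breadth-first growth from a start node
grow_module <- function(graph, m, start) {
  chosen <- character(0)
  frontier <- start
  visited <- character(0)
  while (length(chosen) < m && length(frontier)) {
    v <- frontier[1L]
    frontier <- frontier[-1L]
    if (v %in% visited) next
    visited <- c(visited, v)
    chosen <- c(chosen, v)
    nb <- sort(igraph::neighbors(graph, v)$name)
    frontier <- c(frontier, setdiff(nb, c(visited, frontier)))
  }
  chosen
}

#' Simulate a staged expression series with a planted DNB module
#'
#' Generates an undirected gene network, plants a connected module of
#' `module_size` genes, and draws per-stage cell profiles from a
#' multivariate normal in log space. At every non-critical stage all genes
#' have SD `sigma0` and share an ambient equicorrelation `rho_base` (every
#' gene pair, network edges included, so baseline edge correlations equal
#' `rho_base` and the matrix is positive definite by construction). At the
#' critical stage the module genes switch to SD `sigma_ratio * sigma0`,
#' every within-module pair to correlation `rho_in`, and every
#' module-to-outside pair to `rho_base * rho_out_factor` — the three DNB
#' signatures realized generatively, with exactly no planted signal under
#' the null parameterization (`sigma_ratio = 1`, `rho_in = rho_base`,
#' `rho_out_factor = 1`). Each stage correlation matrix is repaired by
#' eigenvalue clipping and diagonal restoration before scaling to the
#' target SDs and sampling.
#'
#' Latent log values are truncated at zero and transformed with
#' `exp(x) - 1` to count-like raw values, so [normalize_log1p()] recovers
#' the latent scale exactly (up to the rare truncation). With
#' `count_layer = TRUE` Poisson counts with mean `exp(x) - 1` are returned
#' instead.
#'
#' @param config a [simulation_config()].
#' @return List with `expression` (raw [expression_matrix()]), `labels`
#'   (data.frame cell_id/stage_label), `stage_order`, `network`
#'   (a [build_template_network()] object) and `truth` (list: planted
#'   module, critical stage label, reversal gene if any, config).
#' @export
simulate_transition <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  old <- .Random.seed_exists()
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cf$seed)

  genes <- sprintf("G%04d", seq_len(cf$M))
  g <- switch(cf$network_model,
              erdos_renyi = igraph::sample_gnp(cf$M, cf$p),
              barabasi_albert = igraph::sample_pa(cf$M, m = cf$ba_m,
                                                  directed = FALSE))
  igraph::V(g)$name <- genes
  # connect isolated nodes so every gene owns a local network
  iso <- which(igraph::degree(g) == 0)
  for (v in iso) {
    tgt <- sample(setdiff(seq_len(cf$M), v), 1L)
    g <- igraph::add_edges(g, c(v, tgt))
  }

  comp <- igraph::components(g)
  big <- which(comp$membership == which.max(comp$csize))
  start <- genes[sample(big, 1L)]
  module <- grow_module(g, cf$module_size, start)
  if (length(module) < cf$module_size)
    stop("largest component smaller than the requested module size", call. = FALSE)

  A <- as.matrix(igraph::as_adjacency_matrix(g))
  dimnames(A) <- list(genes, genes)
  in_mod <- genes %in% module

  # Baseline: ambient equicorrelation rho_base across all pairs (network
  # edges included at the same value) — positive definite by construction.
  # At t* the module block jumps to rho_in and the whole module-to-outside
  # block is damped by rho_out_factor, planting all three DNB properties
  # with effect sizes visible in group-mean |PCC|; under the null
  # parameterization (sigma_ratio = 1, rho_in = rho_base,
  # rho_out_factor = 1) every stage covariance is identical, so stages are
  # exchangeable.
  cross <- outer(in_mod, !in_mod) | outer(!in_mod, in_mod)
  base_cor <- matrix(cf$rho_base, cf$M, cf$M)
  diag(base_cor) <- 1

  crit_cor <- base_cor
  crit_cor[in_mod, in_mod] <- cf$rho_in
  crit_cor[cross] <- cf$rho_base * cf$rho_out_factor
  diag(crit_cor) <- 1

  sd_base <- rep(cf$sigma0, cf$M)
  sd_crit <- ifelse(in_mod, cf$sigma_ratio * cf$sigma0, cf$sigma0)

  stage_order <- paste0("S", seq_len(cf$T_stages))
  rev_gene <- NULL
  rev_means <- NULL
  if (cf$neighbor_reversal) {
    nb <- setdiff(unique(unlist(lapply(module, function(v)
      igraph::neighbors(g, v)$name))), module)
    if (!length(nb)) stop("no non-module neighbour available for reversal",
                          call. = FALSE)
    rev_gene <- sort(nb)[1L]
    tt <- seq_len(cf$T_stages)
    up <- (tt - 1) / (cf$critical_stage - 1)
    down <- (cf$T_stages - tt) / (cf$T_stages - cf$critical_stage)
    ramp <- ifelse(tt <= cf$critical_stage, up, down)
    ramp[!is.finite(ramp)] <- 1
    rev_means <- cf$reversal_amplitude * ramp
  }

  # repair the correlation matrix (clip eigenvalues, restore unit
  # diagonal), then scale to the target SDs so the planted SDs are exact
  chol_of <- function(cor_mat, sds) {
    C <- stats::cov2cor(nearest_pd(cor_mat))
    S <- diag(sds) %*% C %*% diag(sds)
    tryCatch(chol((S + t(S)) / 2), error = function(e) NULL)
  }
  chol_base <- chol_of(base_cor, sd_base)
  chol_crit <- chol_of(crit_cor, sd_crit)
  if (is.null(chol_base) || is.null(chol_crit))
    stop("covariance repair failed for stage ",
         if (is.null(chol_base)) "baseline" else stage_order[cf$critical_stage],
         call. = FALSE)

  n <- cf$n_per_stage
  vals <- matrix(NA_real_, cf$M, n * cf$T_stages)
  cells <- character(n * cf$T_stages)
  lab <- character(n * cf$T_stages)
  for (t in seq_len(cf$T_stages)) {
    ch <- if (t == cf$critical_stage) chol_crit else chol_base
    z <- matrix(stats::rnorm(n * cf$M), n, cf$M) %*% ch
    x <- t(z) + cf$mu0
    if (!is.null(rev_gene))
      x[match(rev_gene, genes), ] <- x[match(rev_gene, genes), ] + rev_means[t]
    x[x < 0] <- 0
    idx <- (t - 1L) * n + seq_len(n)
    vals[, idx] <- x
    cells[idx] <- sprintf("C%s_%03d", stage_order[t], seq_len(n))
    lab[idx] <- stage_order[t]
  }
  raw <- expm1(vals)
  if (cf$count_layer)
    raw <- matrix(stats::rpois(length(raw), lambda = raw), nrow(raw), ncol(raw))
  dimnames(raw) <- list(genes, cells)

  net <- suppressMessages(
    build_template_network(
      as.data.frame(igraph::as_edgelist(g), stringsAsFactors = FALSE),
      genes))

  list(expression = expression_matrix(raw, normalized = FALSE),
       labels = data.frame(cell_id = cells, stage_label = lab,
                           stringsAsFactors = FALSE),
       stage_order = stage_order,
       network = net,
       truth = list(planted_module = sort(module),
                    critical_stage = stage_order[cf$critical_stage],
                    reversal_gene = rev_gene,
                    config = cf))
}
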