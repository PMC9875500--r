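# Independent brute-force evaluation of the landscape-entropy score, written
# from the defining formulas with explicit loops. Deliberately shares no code
# with the package internals; used as the oracle in equivalence tests.

naive_abs_pcc <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  dx <- sum((x - mx)^2)
  dy <- sum((y - my)^2)
  if (dx == 0 || dy == 0) return(0)
  abs(num / sqrt(dx * dy))
}

naive_sample_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# edges: data.frame(from, to); returns sorted neighbour list per gene
naive_neighbors <- function(edges, gene) {
  nb <- c(edges$to[edges$from == gene], edges$from[edges$to == gene])
  sort(unique(nb))
}

naive_local_score <- function(vals_stage, edges, gene) {
  nbs <- naive_neighbors(edges, gene)
  Q <- length(nbs)
  center <- vals_stage[gene, ]
  s <- naive_sample_sd(center)
  w <- numeric(Q)
  for (i in seq_len(Q)) w[i] <- naive_abs_pcc(center, vals_stage[nbs[i], ])
  sw <- sum(w)
  if (sw == 0) {
    ent <- 0
  } else if (Q == 1) {
    ent <- 1
  } else {
    p <- w / sw
    ent <- 0
    for (i in seq_len(Q)) if (p[i] > 0) ent <- ent + p[i] * log(p[i])
    ent <- -ent / log(Q)
  }
  ent * s
}

# full profile: per-gene-per-stage scores and H_t = sum of R largest
naive_profile <- function(values, stages, stage_order, edges, top_fraction) {
  genes <- sort(unique(c(edges$from, edges$to)))
  M <- length(genes)
  R <- max(1, ceiling(top_fraction * M))
  H <- numeric(length(stage_order))
  names(H) <- stage_order
  local <- matrix(NA_real_, M, length(stage_order),
                  dimnames = list(genes, stage_order))
  for (st in stage_order) {
    vs <- values[, stages == st, drop = FALSE]
    for (g in genes) local[g, st] <- naive_local_score(vs, edges, g)
    H[st] <- sum(sort(local[, st], decreasing = TRUE)[seq_len(R)])
  }
  list(H = H, local = local, R = R)
}

# random small instance: graph with no isolated nodes, staged values with
# occasional constant genes; returns everything both routes need
rand_instance <- function(seed) {
  set.seed(seed)
  M <- sample(4:10, 1)
  Tn <- sample(2:4, 1)
  genes <- sprintf("g%02d", seq_len(M))
  pairs <- t(combn(genes, 2))
  keep <- runif(nrow(pairs)) < 0.45
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      stringsAsFactors = FALSE)
  for (g in genes) {
    if (!g %in% c(edges$from, edges$to)) {
      partner <- sample(setdiff(genes, g), 1)
      edges <- rbind(edges, data.frame(from = min(g, partner),
                                       to = max(g, partner)))
    }
  }
  stage_order <- paste0("t", seq_len(Tn))
  n_per <- sample(8:12, Tn, replace = TRUE)
  stages <- rep(stage_order, n_per)
  cells <- sprintf("c%03d", seq_along(stages))
  values <- matrix(abs(rnorm(M * length(cells))), M,
                   dimnames = list(genes, cells))
  # sprinkle within-stage-constant genes to exercise the degenerate paths
  for (st in stage_order) {
    flat <- genes[runif(M) < 0.1]
    if (length(flat)) values[flat, stages == st] <- runif(length(flat))
  }
  list(values = values, stages = stages, cells = cells,
       stage_order = stage_order, edges = edges, genes = genes)
}

# package-route objects for a rand_instance
instance_series <- function(inst) {
  em <- expression_matrix(inst$values, normalized = TRUE)
  labels <- data.frame(cell_id = inst$cells, stage_label = inst$stages)
  suppressMessages(assemble_stage_series(em, labels, inst$stage_order))
}

instance_network <- function(inst) {
  suppressMessages(build_template_network(inst$edges, inst$genes))
}
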