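test_that("identical configs and seeds reproduce the draw exactly", {
  cfg <- simulation_config(M = 60, n_per_stage = 12, module_size = 8, seed = 99)
  a <- simulate_transition(cfg)
  b <- simulate_transition(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$truth$planted_module, b$truth$planted_module)
  expect_identical(edge_table(a$network), edge_table(b$network))
  # a different seed changes the draw
  c <- simulate_transition(simulation_config(M = 60, n_per_stage = 12,
                                             module_size = 8, seed = 100))
  expect_false(identical(a$expression$values, c$expression$values))
})

test_that("the generated network has no isolated genes and a connected module", {
  sim <- simulate_transition(simulation_config(M = 80, n_per_stage = 10,
                                               module_size = 10, seed = 5))
  deg <- igraph::degree(sim$network$graph)
  expect_true(all(deg >= 1))
  sub <- igraph::induced_subgraph(sim$network$graph,
                                  sim$truth$planted_module)
  expect_true(igraph::is_connected(sub))
  expect_identical(length(sim$truth$planted_module), 10L)
})

test_that("the null parameterization removes the planted signal", {
  sim <- simulate_transition(simulation_config(
    sigma_ratio = 1, rho_in = 0.1, rho_out_factor = 1, seed = 8))
  ss <- suppressMessages(assemble_stage_series(
    normalize_log1p(sim$expression), sim$labels, sim$stage_order))
  mod <- sim$truth$planted_module
  sd_by_stage <- vapply(sim$stage_order, function(st) {
    v <- ss$matrix$values[mod, ss$stages == st, drop = FALSE]
    mean(apply(v, 1, sd))
  }, numeric(1))
  # per-stage mean module SD statistically indistinguishable across stages
  expect_lt(max(sd_by_stage) / min(sd_by_stage), 1.15)
})

test_that("empirical module SD inflation approaches sigma_ratio at large n", {
  sim <- simulate_transition(simulation_config(n_per_stage = 400, seed = 12))
  ss <- suppressMessages(assemble_stage_series(
    normalize_log1p(sim$expression), sim$labels, sim$stage_order))
  mod <- sim$truth$planted_module
  sd_at <- function(st) {
    v <- ss$matrix$values[mod, ss$stages == st, drop = FALSE]
    mean(apply(v, 1, sd))
  }
  ratio <- sd_at("S4") / mean(sapply(c("S1", "S2", "S3", "S5", "S6"), sd_at))
  expect_equal(ratio, 3, tolerance = 0.1)
})

test_that("raw values are count-like and recover the latent log scale", {
  sim <- simulate_transition(simulation_config(M = 50, n_per_stage = 10,
                                               module_size = 6, seed = 2))
  expect_true(all(sim$expression$values >= 0))
  expect_false(sim$expression$normalized)
  norm <- normalize_log1p(sim$expression)
  expect_true(all(is.finite(norm$values)))

  pois <- simulate_transition(simulation_config(M = 50, n_per_stage = 10,
                                                module_size = 6, seed = 2,
                                                count_layer = TRUE))
  expect_true(all(pois$expression$values == round(pois$expression$values)))
})

test_that("the reversal gene is a module neighbour outside the module", {
  sim <- simulate_transition(simulation_config(M = 60, n_per_stage = 10,
                                               module_size = 8, seed = 4,
                                               neighbor_reversal = TRUE))
  rg <- sim$truth$reversal_gene
  expect_false(rg %in% sim$truth$planted_module)
  nb <- find_dnb_neighbors(sim$network, sim$truth$planted_module)
  expect_true(rg %in% nb)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(module_size = 300), "module_size")
  expect_error(simulation_config(critical_stage = 9), "critical_stage")
  expect_error(simulation_config(rho_in = 0.05, rho_base = 0.1))
  expect_error(simulation_config(n_per_stage = 5), "n_per_stage")
  expect_error(simulation_config(sigma_ratio = 0.5), "sigma_ratio")
})
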