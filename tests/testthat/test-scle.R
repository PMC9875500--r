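test_that("absolute Pearson correlation follows the stated conventions", {
  expect_equal(pearson_abs(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_abs(c(1, 2, 3), c(3, 2, 1)), 1)
  expect_equal(pearson_abs(c(1, 2, 3), c(5, 5, 5)), 0)
  expect_error(pearson_abs(1:3, 1:4), "mismatch")
  expect_error(pearson_abs(1:2, 1:2), "at least 3")

  set.seed(11)
  x <- rnorm(20)
  y <- rnorm(20)
  expect_equal(pearson_abs(x, y), naive_abs_pcc(x, y), tolerance = 1e-12)
})

test_that("local score degenerate cases follow the entropy conventions", {
  # center constant within the stage: sd = 0 so score = 0
  set.seed(21)
  vals <- rbind(HUB = rep(2, 16), L1 = rnorm(16), L2 = rnorm(16),
                L3 = rnorm(16), L4 = rnorm(16))
  colnames(vals) <- sprintf("c%02d", 1:16)
  ss <- series_from_matrix(abs(vals), 2)
  net <- star_network()
  out <- local_scle(ss, local_network(net, "HUB"), "t1")
  expect_equal(out$score, 0)
  expect_equal(out$sd, 0)

  # all neighbours perfectly correlated with the center: uniform weights,
  # entropy 1, score = sd
  x <- seq_len(16)
  vals2 <- rbind(HUB = x, L1 = 2 * x, L2 = 100 - x, L3 = 3 * x + 1,
                 L4 = -0.5 * x + 40)
  colnames(vals2) <- sprintf("c%02d", 1:16)
  ss2 <- series_from_matrix(vals2, 2)
  out2 <- local_scle(ss2, local_network(net, "HUB"), "t1")
  expect_equal(out2$entropy, 1)
  expect_equal(out2$score, out2$sd)
  expect_equal(out2$weights, rep(0.25, 4))

  # single neighbour: entropy 1 by the Q = 1 convention
  leaf <- local_scle(ss2, local_network(net, "L1"), "t1")
  expect_equal(leaf$entropy, 1)
  expect_equal(leaf$score, leaf$sd)
})

test_that("entropy of planted weights (0.7, 0.2, 0.1) matches brute force", {
  # construct neighbours whose empirical |PCC| with the center is exactly
  # 0.7 / 0.2 / 0.1 via an orthonormal basis
  set.seed(31)
  n <- 12
  z1 <- scale(rnorm(n))[, 1]
  raw <- rnorm(n)
  z2 <- raw - sum(raw * z1) / sum(z1^2) * z1
  z2 <- scale(z2)[, 1]   # centre and scale so |PCC(z1, nb)| is exact
  w <- c(0.7, 0.2, 0.1)
  nb <- sapply(w, function(wi) wi * z1 + sqrt(1 - wi^2) * z2)
  block <- rbind(HUB = z1, L1 = nb[, 1], L2 = nb[, 2], L3 = nb[, 3])
  vals <- cbind(block, block)   # two identical stages
  colnames(vals) <- sprintf("c%02d", seq_len(2 * n))
  net <- star_network(leaves = paste0("L", 1:3))
  ss <- series_from_matrix(vals, 2)
  out <- local_scle(ss, local_network(net, "HUB"), "t1")
  expect_equal(out$weights, w, tolerance = 1e-10)
  # frozen value computed with the independent loop oracle
  expect_equal(out$entropy, 0.7298467, tolerance = 1e-6)
  expect_equal(out$score, out$entropy * out$sd)
})

test_that("stage scores sum the R largest local scores with R = ceil(fraction * M)", {
  inst <- rand_instance(101)
  # force M = 40 genes so R = ceil(0.05 * 40) = 2
  set.seed(101)
  genes <- sprintf("g%02d", 1:40)
  edges <- data.frame(from = genes[1:39], to = genes[2:40])
  vals <- matrix(abs(rnorm(40 * 20)), 40,
                 dimnames = list(genes, sprintf("c%02d", 1:20)))
  ss <- series_from_matrix(vals, 2)
  net <- suppressMessages(build_template_network(edges, genes))
  fit <- scle(ss, net, top_fraction = 0.05)
  expect_identical(fit$R, 2L)
  for (st in fit$stage_order) {
    sc <- fit$local_scores[fit$local_scores$stage == st, ]
    expect_equal(unname(fit$stage_scores[st]),
                 sum(sort(sc$score, decreasing = TRUE)[1:2]))
    expect_identical(length(fit$top_genes[[st]]), 2L)
  }
  # top_fraction = 1 keeps every gene
  expect_identical(scle(ss, net, top_fraction = 1)$R, 40L)
})

test_that("critical-stage calling uses argmax with earliest-tie and boundary flags", {
  h <- c(s1 = 1, s2 = 1, s3 = 1, s4 = 5, s5 = 1, s6 = 1)
  out <- detect_critical_stage(h)
  expect_identical(out$critical_stage, "s4")
  expect_equal(out$fold_change, 5)
  expect_false(out$end_of_series_warning)

  tie <- detect_critical_stage(c(a = 2, b = 2))
  expect_identical(tie$critical_stage, "a")
  expect_equal(tie$fold_change, Inf)

  rising <- detect_critical_stage(c(a = 1, b = 2, c = 3, d = 4))
  expect_identical(rising$critical_stage, "d")
  expect_true(rising$end_of_series_warning)

  expect_error(detect_critical_stage(c(a = 1)), "two stages")
})

test_that("permutation p-values are deterministic under a fixed seed", {
  inst <- rand_instance(7)
  ss <- instance_series(inst)
  net <- instance_network(inst)
  fit <- scle(ss, net)
  p1 <- scle_permutation_test(fit, ss, net, B = 19, seed = 5)
  p2 <- scle_permutation_test(fit, ss, net, B = 19, seed = 5)
  expect_identical(p1$p.value, p2$p.value)
  expect_identical(p1$perm_max, p2$perm_max)
  expect_gte(p1$p.value, 1 / 20)
  expect_lte(p1$p.value, 1)
  # p = (1 + #{perm >= obs}) / (B + 1)
  expect_equal(p1$p.value, (1 + sum(p1$perm_max >= max(fit$stage_scores))) / 20)
  expect_error(scle_permutation_test(fit, ss, net, B = 0), "at least 1")
})

test_that("vectorized fit agrees with per-gene local_scle on small instances", {
  for (seed in c(3, 17)) {
    inst <- rand_instance(seed)
    ss <- instance_series(inst)
    net <- instance_network(inst)
    fit <- scle(ss, net)
    for (g in net$nodes) {
      ln <- local_network(net, g)
      for (st in ss$stage_order) {
        one <- local_scle(ss, ln, st)
        row <- fit$local_scores[fit$local_scores$gene == g &
                                  fit$local_scores$stage == st, ]
        expect_equal(row$score, one$score, tolerance = 1e-12)
        expect_equal(row$entropy, one$entropy, tolerance = 1e-12)
      }
    }
  }
})
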