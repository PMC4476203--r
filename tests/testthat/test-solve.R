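expect_solve_matches <- function(toy, tol = 1e-10) {
  fit <- solve_network(toy$network)
  nodes <- dplyr::inner_join(fit$nodes, toy$expected$nodes, by = "node_id")
  expect_equal(nodes$pressure_Pa.x, nodes$pressure_Pa.y, tolerance = tol)
  edges <- dplyr::inner_join(fit$edges, toy$expected$edges, by = "vessel_id")
  expect_equal(edges$flow_ml_s.x, edges$flow_ml_s.y, tolerance = tol)
  invisible(fit)
}

test_that("single vessel obeys the hydraulic Ohm analogue P = R Q", {
  toy <- make_toy("single_edge", q_ml_s = 3)
  fit <- expect_solve_matches(toy)
  res <- vessel_resistances(toy$network)$resistance
  expect_equal(fit$nodes$pressure_Pa[fit$nodes$node_id == "n1"],
               res * 3e-6, tolerance = 1e-12)
})

test_that("parallel branches split flow in proportion to opposite resistance", {
  toy <- make_toy("parallel_pair", q_ml_s = 6)
  fit <- expect_solve_matches(toy)
  res <- vessel_resistances(toy$network)$resistance
  f <- fit$edges$flow_ml_s
  expect_equal(f[1] / f[2], res[2] / res[1], tolerance = 1e-10)
  expect_equal(sum(f), 6, tolerance = 1e-10)
})

test_that("wye and chain and ladder toys match their closed forms", {
  expect_solve_matches(make_toy("wye"))
  expect_solve_matches(make_toy("series_chain", n = 5))
  expect_solve_matches(make_toy("ladder", n = 3))
  expect_solve_matches(make_toy("ladder", n = 6))
})

test_that("mass is conserved at every node and globally", {
  for (seed in 1:10) {
    net <- make_random(n_nodes = sample(4:12, 1), seed = seed,
                       n_sources = sample(1:3, 1))
    fit <- solve_network(net)
    total <- fit$total_inflow
    expect_lte(fit$residual, 1e-10 * total)
    # flow out through reference nodes equals total injected flow
    v <- net$vessels
    refs <- net$nodes$id[net$nodes$is_reference]
    out <- sum(fit$edges$flow_ml_s[v$downstream_node %in% refs]) -
      sum(fit$edges$flow_ml_s[v$upstream_node %in% refs])
    expect_equal(out * 1e-6, total, tolerance = 1e-10)
  }
})

test_that("the solve is linear: superposition and homogeneity hold", {
  net <- make_random(n_nodes = 10, seed = 7, n_sources = 3)
  full <- solve_network(net)
  parts <- lapply(seq_len(nrow(net$inputs)), function(i) {
    one <- net
    one$inputs <- net$inputs[i, ]
    solve_network(one)
  })
  p_sum <- Reduce(`+`, lapply(parts, function(f) f$nodes$pressure_Pa))
  expect_equal(full$nodes$pressure_Pa, p_sum, tolerance = 1e-9)
  f_sum <- Reduce(`+`, lapply(parts, function(f) f$edges$flow_ml_s))
  expect_equal(full$edges$flow_ml_s, f_sum, tolerance = 1e-9)

  scaled <- net
  scaled$inputs$rate_ml_s <- scaled$inputs$rate_ml_s * 3.5
  sfit <- solve_network(scaled)
  expect_equal(sfit$nodes$pressure_Pa, 3.5 * full$nodes$pressure_Pa,
               tolerance = 1e-12)
  expect_equal(sfit$edges$flow_ml_s, 3.5 * full$edges$flow_ml_s,
               tolerance = 1e-12)
})

test_that("source pressure is monotone in any single edge resistance", {
  # Rayleigh monotonicity: increasing one resistance cannot decrease the
  # pressure at the (single) source node
  for (seed in 1:8) {
    net <- make_random(n_nodes = sample(5:10, 1), seed = 100 + seed,
                       n_sources = 1)
    src <- net$inputs$node_id
    p0 <- solve_network(net)$nodes
    p0 <- p0$pressure_Pa[p0$node_id == src]
    k <- 1 + (seed %% nrow(net$vessels))
    worse <- net
    # narrower vessel = strictly larger resistance
    worse$vessels$diameter_cm[k] <- worse$vessels$diameter_cm[k] * 0.6
    p1 <- solve_network(worse)$nodes
    p1 <- p1$pressure_Pa[p1$node_id == src]
    expect_gte(p1, p0 - 1e-12 * max(p0, 1))
  }
})

test_that("direct solve agrees with the relaxation oracle on small networks", {
  for (seed in 1:6) {
    net <- make_random(n_nodes = sample(4:12, 1), seed = 200 + seed,
                       n_sources = sample(1:2, 1))
    fit <- solve_network(net)
    oracle <- relaxation_oracle(net)
    scale <- max(abs(oracle))
    expect_lt(max(abs(fit$nodes$pressure_Pa - oracle[fit$nodes$node_id])),
              1e-8 * scale)
  }
})

test_that("the two reference-separated systems are hydraulically decoupled", {
  net <- reference_anatomy()
  base <- solve_network(net)
  lower_nodes <- c(paste0("az", 1:12), paste0("t", 1:12), paste0("qt", 1:12),
                   "tlj", "l1", "l2", "ql1", "ql2",
                   "w1", "w2", "k1", "k2", "fem")
  # perturb above the heart: lower system bit-identical
  upper_stenosed <- apply_stenosis(net, "IJV_l", 0.6)
  fit <- solve_network(upper_stenosed)
  expect_identical(
    fit$nodes$pressure_Pa[fit$nodes$node_id %in% lower_nodes],
    base$nodes$pressure_Pa[base$nodes$node_id %in% lower_nodes]
  )
  # perturb below: upper system bit-identical
  lower_stenosed <- apply_stenosis(net, "AZ3", 0.6)
  fit2 <- solve_network(lower_stenosed)
  upper_sel <- !(base$nodes$node_id %in% lower_nodes)
  expect_identical(fit2$nodes$pressure_Pa[upper_sel],
                   base$nodes$pressure_Pa[upper_sel])
})

test_that("a source with no drainage path is rejected by name", {
  toy <- make_toy("single_edge")
  blocked <- apply_stenosis(toy$network, "v1", 1)
  expect_error(solve_network(blocked), "no drainage path.*n1")
})

test_that("solve results serialize to the canonical CSV pair", {
  fit <- solve_network(make_toy("wye")$network)
  dir <- withr::local_tempdir()
  paths <- write_solve_csv(fit, file.path(dir, "wye"))
  nodes <- readr::read_csv(paths[1], show_col_types = FALSE)
  edges <- readr::read_csv(paths[2], show_col_types = FALSE)
  expect_named(nodes, c("node_id", "pressure_Pa"))
  expect_named(edges, c("vessel_id", "flow_ml_s", "delta_p_Pa", "antegrade"))
  expect_equal(nrow(edges), 3)
})

test_that("tidy and glance expose the solve in tabular form", {
  fit <- solve_network(make_toy("parallel_pair")$network)
  expect_named(tidy(fit), c("vessel_id", "name", "district", "flow_ml_s",
                            "delta_p_Pa", "antegrade"))
  nd <- tidy(fit, "nodes")
  expect_equal(nd$pressure_mmHg, nd$pressure_Pa / 133.322)
  g <- glance(fit)
  expect_equal(g$n_vessels, 2)
  expect_equal(g$total_inflow_ml_s, 5, tolerance = 1e-12)
  expect_equal(g$n_retrograde, 0)
})
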