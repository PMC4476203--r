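# A wye with one branch deliberately oriented against its flow, so the solve
# reports a negative (retrograde-by-convention) flow on that branch.
reversed_wye <- function() {
  toy <- make_toy("wye")
  net <- toy$network
  i <- net$vessels$id == "v3"
  u <- net$vessels$upstream_node[i]
  net$vessels$upstream_node[i] <- net$vessels$downstream_node[i]
  net$vessels$downstream_node[i] <- u
  net
}

test_that("reflux detection is a sign test with a stagnation band", {
  fit <- solve_network(reversed_wye())
  r <- detect_reflux(fit)
  expect_equal(r$vessel_id, "v3")
  expect_lt(r$flow_ml_s, 0)
  allv <- detect_reflux(fit, all = TRUE)
  expect_setequal(allv$status[allv$vessel_id %in% c("v1", "v2")], "antegrade")
  # a tolerance wider than the flow classes it stagnant, not refluent
  wide <- detect_reflux(fit, tolerance = 1, all = TRUE)  # 1 m^3/s = 1e6 ml/s
  expect_setequal(wide$status, "stagnant")
  expect_equal(nrow(detect_reflux(fit, tolerance = 1)), 0)
})

test_that("reflux calls are invariant to tolerance across float-noise scales", {
  net <- reference_anatomy()
  scenarios <- list(
    solve_network(net),
    solve_network(apply_stenosis(net, c("IJV_l", "IJV_r"), 0.95)),
    solve_network(apply_stenosis(net, paste0("AZ", 1:4), 0.8))
  )
  for (fit in scenarios) {
    calls <- lapply(c(1e-12, 1e-10, 1e-9), function(tol) {
      detect_reflux(fit, tolerance = tol)$vessel_id
    })
    expect_identical(calls[[1]], calls[[2]])
    expect_identical(calls[[1]], calls[[3]])
  }
})

test_that("relative change is zero at identity, flags zero baselines", {
  toy <- make_toy("wye")$network
  base <- solve_network(toy)
  rc <- relative_change(base, base)
  expect_true(all(rc$rel_change[rc$defined] == 0))
  doubled <- toy
  doubled$inputs$rate_ml_s <- doubled$inputs$rate_ml_s * 2
  rc2 <- relative_change(base, solve_network(doubled))
  expect_equal(rc2$rel_change[rc2$defined], rep(1, sum(rc2$defined)),
               tolerance = 1e-12)
  # reference nodes have zero baseline pressure: flagged, not divided
  expect_true(all(!rc2$defined[rc2$id == "ground" &
                                 rc2$quantity == "pressure_Pa"]))
  other <- solve_network(make_toy("single_edge")$network)
  expect_error(relative_change(base, other), "different topologies")
})

test_that("threshold search returns adjacent first-true/last-false grid points", {
  toy <- make_toy("single_edge")$network
  sw <- run_sweep(toy, sweep_axis("v1", c(0, 0.5, 0.9)))
  th <- find_threshold(sw, pred_pressure_ratio("n1", 2), "pressure doubled")
  # (1 - 0.5)^-4 = 16 >= 2, so the predicate first holds at 0.5
  expect_true(th$reached)
  expect_equal(th$first_true, 0.5)
  expect_equal(th$last_false, 0)
  expect_equal(th$n_transitions, 1)

  none <- find_threshold(sw, pred_any_reflux(), "any reflux")
  expect_false(none$reached)
  expect_true(is.na(none$first_true))

  base_only <- run_sweep(toy, sweep_axis("v1", 0))
  nr <- find_threshold(base_only, pred_any_reflux(), "any reflux")
  expect_false(nr$reached)
})

test_that("threshold search reports every transition of a non-monotone predicate", {
  toy <- make_toy("single_edge")$network
  sw <- run_sweep(toy, sweep_axis("v1", c(0, 0.3, 0.6, 0.9)))
  flaky <- function(fit, baseline) {
    r <- 1 - fit$network$vessels$diameter_cm[1] /
      baseline$network$vessels$diameter_cm[1]
    r > 0.2 && r < 0.5 || r > 0.8
  }
  th <- find_threshold(sw, flaky, "band predicate")
  expect_equal(th$n_transitions, 2)
  expect_equal(th$transitions[[1]], c(0.3, 0.9))
  expect_equal(th$first_true, 0.3)
  expect_equal(th$last_false, 0.6)
})

test_that("per-vessel Reynolds table uses network geometry", {
  net <- make_toy("parallel_pair")$network
  fit <- solve_network(net)
  rn <- reynolds_numbers(fit)
  i <- match(rn$vessel_id, net$vessels$id)
  expect_equal(
    rn$reynolds,
    4 * 1060 * abs(rn$flow_ml_s * 1e-6) /
      (pi * 0.003 * net$vessels$diameter_cm[i] / 100),
    tolerance = 1e-12
  )
  expect_true(all(diff(rn$reynolds) <= 0))
})

test_that("exact signed-rank p-values match hand-derived cases", {
  # five measurements all above the model value: V = 15, p = 2/32
  res <- signed_rank_compare(c(5.1, 5.4, 5.2, 5.9, 5.3), 5)
  expect_equal(res$p_value, 0.0625)
  expect_equal(res$statistic, 15)
  expect_equal(res$n, 5L)
  # a single non-zero difference: p = 2 * (1/2) = 1
  expect_equal(signed_rank_compare(7.3, 7)$p_value, 1)
  # symmetric pair around the model value: statistic at the centre, p = 1
  sym <- signed_rank_compare(c(6.5, 7.5), 7)
  expect_equal(sym$p_value, 1)
  # all differences zero: p = 1 flagged with n = 0
  zero <- signed_rank_compare(c(2, 2, 2), 2)
  expect_equal(zero$n, 0L)
  expect_equal(zero$n_zero, 3L)
  expect_equal(zero$p_value, 1)
})

test_that("signed-rank p-values match brute-force enumeration on random samples", {
  withr::local_seed(42)
  for (k in 1:200) {
    n <- sample(2:10, 1)
    x <- round(stats::rnorm(n, sd = 2), sample(0:1, 1))  # induces ties often
    m <- round(stats::rnorm(1), 1)
    if (all(x == m)) next
    expect_equal(signed_rank_compare(x, m)$p_value,
                 brute_force_signed_rank(x, m),
                 tolerance = 1e-12, label = paste("case", k))
  }
})

test_that("signed-rank agrees with the classical exact test when tie-free", {
  withr::local_seed(99)
  for (k in 1:50) {
    n <- sample(4:20, 1)
    x <- stats::rnorm(n)
    p_ref <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = TRUE,
                                                 correct = FALSE)$p.value)
    expect_equal(signed_rank_compare(x, 0)$p_value, p_ref,
                 tolerance = 1e-10, label = paste("case", k))
  }
})

test_that("compare_flows classifies vessels and skips unknown ones", {
  net <- make_toy("wye")$network
  fit <- solve_network(net)
  model_v2 <- fit$edges$flow_ml_s[fit$edges$vessel_id == "v2"]
  measured <- tibble::tibble(
    vessel = rep(c("v2", "ghost"), each = 6),
    subject_id = rep(1:6, 2),
    flow_ml_s = c(model_v2 + c(-0.02, 0.01, -0.01, 0.03, -0.03, 0.02),
                  rep(9, 6))
  )
  expect_warning(cmp <- compare_flows(measured, fit), "ghost")
  expect_equal(cmp$vessel, "v2")
  expect_gt(cmp$p_value, 0.1)
  expect_equal(cmp$class, "ns")
  # strongly shifted measurements become significant
  shifted <- tibble::tibble(vessel = "v2", subject_id = 1:8,
                            flow_ml_s = model_v2 + seq(1, 2, length.out = 8))
  cmp2 <- compare_flows(shifted, fit)
  expect_lt(cmp2$p_value, 0.05)
  expect_equal(cmp2$class, "significant")
  expect_error(compare_flows(measured[0, ], fit), "no rows")
})
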