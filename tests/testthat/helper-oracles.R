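# Independent oracles used across the suite. These deliberately avoid the
# package's direct sparse solve: the relaxation oracle is a Gauss-Seidel
# fixed-point iteration on node pressures, the signed-rank oracle a literal
# enumeration of all 2^n sign assignments.

# Gauss-Seidel relaxation on the nodal balance equations, run to `tol`
# (relative to the pressure scale). Reference nodes pinned at their fixed
# pressures. Returns pressures named by node id.
relaxation_oracle <- function(net, tol = 1e-12, max_iter = 5e5) {
  v <- net$vessels
  n <- net$nodes
  mu <- net$viscosity
  g <- 1 / venonet::poiseuille_resistance(v$length_cm / 100,
                                          v$diameter_cm / 100, mu)
  ids <- n$id
  p <- stats::setNames(rep(0, length(ids)), ids)
  p[n$is_reference] <- n$reference_pressure[n$is_reference]
  inj <- stats::setNames(rep(0, length(ids)), ids)
  for (i in seq_len(nrow(net$inputs))) {
    inj[net$inputs$node_id[i]] <-
      inj[net$inputs$node_id[i]] + net$inputs$rate_ml_s[i] * 1e-6
  }
  # adjacency as index lists
  nbr <- lapply(ids, function(x) {
    up <- which(v$upstream_node == x)
    dn <- which(v$downstream_node == x)
    list(other = c(v$downstream_node[up], v$upstream_node[dn]),
         g = c(g[up], g[dn]))
  })
  names(nbr) <- ids
  free <- ids[!n$is_reference]
  for (iter in seq_len(max_iter)) {
    delta <- 0
    for (x in free) {
      nb <- nbr[[x]]
      if (length(nb$g) == 0) next
      new_p <- (sum(nb$g * p[nb$other]) + inj[x]) / sum(nb$g)
      delta <- max(delta, abs(new_p - p[x]))
      p[x] <- new_p
    }
    scale <- max(abs(p), 1e-30)
    if (delta / scale < tol) break
  }
  p
}

# Exact one-sample signed-rank two-sided p-value by explicit enumeration of
# every sign assignment (feasible for n <= ~12).
brute_force_signed_rank <- function(measured, model_value) {
  d <- measured - model_value
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  upper <- mean(vs >= v_obs - 1e-9)
  lower <- mean(vs <= v_obs + 1e-9)
  min(1, 2 * min(upper, lower))
}

# Two-vessels-in-series toy CSV + config pair written to a temp dir;
# returns the two paths.
write_toy_anatomy <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  csv <- file.path(dir, "toy.csv")
  cfg <- file.path(dir, "toy_config.json")
  writeLines(c(
    "id,name,side,district,length_cm,diameter_cm,upstream_node,downstream_node",
    "a,vessel a,midline,cervical,10,1,n1,n2",
    "b,vessel b,midline,cervical,5,0.8,n2,ground"
  ), csv)
  writeLines(paste0(
    '{"reference_nodes": ["ground"], "viscosity_cP": 3, ',
    '"flow_inputs": [{"node": "n1", "ml_s": 5, "label": "Q_c"}]}'
  ), cfg)
  c(anatomy = csv, config = cfg)
}
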