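#' Toy networks with closed-form solutions
#'
#' Small fixed networks whose steady-state pressures and flows are derived
#' analytically (series/parallel reduction), independently of the nodal
#' solver, so they can serve as oracles in tests.
#'
#' Kinds:
#' * `single_edge` — one vessel from a source node to the reference;
#'   `P_source = R Q`.
#' * `series_chain` — `n` vessels in series; the source flow traverses all.
#' * `parallel_pair` — two branches between source and reference; flow splits
#'   in proportion to the opposite branch's resistance.
#' * `wye` — a stem feeding two parallel branches.
#' * `ladder` — `n` series rungs each with a shunt leg to the reference,
#'   solved by backward equivalent-resistance recursion.
#'
#' @param kind One of `"single_edge"`, `"series_chain"`, `"parallel_pair"`,
#'   `"wye"`, `"ladder"`.
#' @param n Number of segments for `series_chain` / `ladder` (default 3).
#' @param q_ml_s Source inflow in ml/s (default 5).
#' @param lengths_cm,diameters_cm Optional geometry overrides (recycled to
#'   the kind's edge count).
#' @return List with `network` (a [venous_network()]) and `expected` (list of
#'   tibbles `nodes` (`node_id`, `pressure_Pa`) and `edges` (`vessel_id`,
#'   `flow_ml_s`)).
#' @examples
#' toy <- make_toy("wye")
#' fit <- solve_network(toy$network)
#' all.equal(tidy(fit)$flow_ml_s, toy$expected$edges$flow_ml_s)
#' @export
make_toy <- function(kind = c("single_edge", "series_chain", "parallel_pair",
                              "wye", "ladder"),
                     n = 3, q_ml_s = 5,
                     lengths_cm = NULL, diameters_cm = NULL) {
  kind <- match.arg(kind)
  q <- q_ml_s * M3S_PER_MLS
  mu <- 0.003

  geom <- function(n_edges, default_l, default_d) {
    l <- rep(lengths_cm %||% default_l, length.out = n_edges)
    d <- rep(diameters_cm %||% default_d, length.out = n_edges)
    list(l = l, d = d,
         r = poiseuille_resistance(l / CM_PER_M, d / CM_PER_M, mu))
  }
  vtab <- function(id, up, dn, l, d) {
    tibble(id = id, name = id, side = "midline", district = "connective",
           length_cm = l, diameter_cm = d, upstream_node = up,
           downstream_node = dn)
  }
  inputs <- function(node) tibble(node_id = node, rate_ml_s = q_ml_s,
                                  label = "Q_c")

  if (kind == "single_edge") {
    g <- geom(1, 10, 0.8)
    net <- venous_network(vtab("v1", "n1", "ground", g$l, g$d),
                          inputs("n1"), "ground")
    expected <- list(
      nodes = tibble(node_id = c("n1", "ground"),
                     pressure_Pa = c(g$r * q, 0)),
      edges = tibble(vessel_id = "v1", flow_ml_s = q_ml_s)
    )
  } else if (kind == "series_chain") {
    g <- geom(n, 10, seq(0.6, 1.0, length.out = n))
    ids <- paste0("v", seq_len(n))
    up <- c("n1", paste0("m", seq_len(n - 1)))
    dn <- c(paste0("m", seq_len(n - 1)), "ground")
    net <- venous_network(vtab(ids, up, dn, g$l, g$d), inputs("n1"), "ground")
    p <- rev(cumsum(rev(g$r))) * q        # pressure at upstream of each edge
    expected <- list(
      nodes = tibble(node_id = c(up, "ground"), pressure_Pa = c(p, 0)),
      edges = tibble(vessel_id = ids, flow_ml_s = rep(q_ml_s, n))
    )
  } else if (kind == "parallel_pair") {
    g <- geom(2, c(10, 12), c(0.7, 0.9))
    net <- venous_network(
      vtab(c("v1", "v2"), "n1", "ground", g$l, g$d), inputs("n1"), "ground"
    )
    rp <- parallel_resistance(g$r)
    expected <- list(
      nodes = tibble(node_id = c("n1", "ground"), pressure_Pa = c(rp * q, 0)),
      edges = tibble(vessel_id = c("v1", "v2"),
                     flow_ml_s = q_ml_s * rev(g$r) / sum(g$r))
    )
  } else if (kind == "wye") {
    g <- geom(3, c(8, 10, 12), c(0.8, 0.6, 0.7))
    net <- venous_network(
      vtab(c("v1", "v2", "v3"), c("n1", "m", "m"),
           c("m", "ground", "ground"), g$l, g$d),
      inputs("n1"), "ground"
    )
    rp <- parallel_resistance(g$r[2:3])
    pm <- rp * q
    expected <- list(
      nodes = tibble(node_id = c("n1", "m", "ground"),
                     pressure_Pa = c(pm + g$r[1] * q, pm, 0)),
      edges = tibble(
        vessel_id = c("v1", "v2", "v3"),
        flow_ml_s = c(q_ml_s,
                      q_ml_s * g$r[3] / sum(g$r[2:3]),
                      q_ml_s * g$r[2] / sum(g$r[2:3]))
      )
    )
  } else { # ladder
    gs <- geom(n, 6, 0.6)                               # series rungs
    gh <- list(l = rep(9, n), d = rep(0.5, n))
    gh$r <- poiseuille_resistance(gh$l / CM_PER_M, gh$d / CM_PER_M, mu)
    xs <- paste0("x", seq_len(n))
    series_ids <- paste0("s", seq_len(n - 1))
    shunt_ids <- paste0("h", seq_len(n))
    vessels <- dplyr::bind_rows(
      if (n > 1) vtab(series_ids, xs[-n], xs[-1],
                      gs$l[-n], gs$d[-n]) else NULL,
      vtab(shunt_ids, xs, "ground", gh$l, gh$d)
    )
    net <- venous_network(vessels, inputs("x1"), "ground")
    # backward equivalent resistance, then forward pressure/flow recursion
    req <- numeric(n)
    req[n] <- gh$r[n]
    if (n > 1) {
      for (i in (n - 1):1) {
        req[i] <- parallel_resistance(c(gh$r[i], gs$r[i] + req[i + 1]))
      }
    }
    p <- numeric(n)
    fser <- numeric(max(n - 1, 0))
    fin <- q
    p[1] <- fin * req[1]
    if (n > 1) {
      for (i in 1:(n - 1)) {
        shunt <- p[i] / gh$r[i]
        fser[i] <- fin - shunt
        p[i + 1] <- p[i] - fser[i] * gs$r[i]
        fin <- fser[i]
      }
    }
    expected <- list(
      nodes = tibble(node_id = c(xs, "ground"), pressure_Pa = c(p, 0)),
      edges = tibble(
        vessel_id = c(if (n > 1) series_ids else character(), shunt_ids),
        flow_ml_s = c(if (n > 1) fser / M3S_PER_MLS else numeric(),
                      p / gh$r / M3S_PER_MLS)
      )
    )
  }
  list(network = net, expected = expected)
}

#' Random connected test networks
#'
#' Generates a reproducible random venous network: a random spanning tree
#' (guaranteeing connectivity) plus extra edges up to the requested density,
#' geometry drawn from ranges bracketing venous dimensions (D in
#' \[0.05, 1.5\] cm, L in \[0.5, 30\] cm), with the last node(s) as
#' zero-pressure references and sources attached to random non-reference
#' nodes. Always passes [validate_network()]. The global RNG state is left
#' untouched.
#'
#' @param n_nodes Number of nodes (4-12 typical).
#' @param edge_density Fraction of additional node pairs (beyond the spanning
#'   tree) to connect (default 0.3).
#' @param seed Integer seed; same seed, same network.
#' @param n_sources,n_refs Number of source / reference nodes (defaults 1, 1).
#' @return A [venous_network()].
#' @export
make_random <- function(n_nodes = 8, edge_density = 0.3, seed = 1,
                        n_sources = 1, n_refs = 1) {
  if (n_nodes < 3) abort("`n_nodes` must be >= 3.")
  if (n_sources + n_refs > n_nodes) {
    abort("more sources + references than nodes.")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  ids <- paste0("n", seq_len(n_nodes))
  # random spanning tree: connect node k to a uniformly chosen earlier node
  up <- character(0); dn <- character(0)
  for (k in 2:n_nodes) {
    up <- c(up, ids[k])
    dn <- c(dn, ids[sample.int(k - 1, 1)])
  }
  pairs <- utils::combn(n_nodes, 2)
  have <- paste(pmin(match(up, ids), match(dn, ids)),
                pmax(match(up, ids), match(dn, ids)))
  avail <- which(!paste(pairs[1, ], pairs[2, ]) %in% have)
  n_extra <- min(length(avail), round(edge_density * length(avail)))
  if (n_extra > 0) {
    pick <- sample(avail, n_extra)
    up <- c(up, ids[pairs[1, pick]])
    dn <- c(dn, ids[pairs[2, pick]])
  }
  n_edges <- length(up)
  vessels <- tibble(
    id = paste0("e", seq_len(n_edges)),
    name = paste0("e", seq_len(n_edges)),
    side = "midline", district = "connective",
    length_cm = stats::runif(n_edges, 0.5, 30),
    diameter_cm = stats::runif(n_edges, 0.05, 1.5),
    upstream_node = up, downstream_node = dn
  )
  refs <- ids[(n_nodes - n_refs + 1):n_nodes]
  src <- sample(setdiff(ids, refs), n_sources)
  inputs <- tibble(node_id = src,
                   rate_ml_s = stats::runif(n_sources, 1, 10),
                   label = paste0("Q_", seq_len(n_sources)))
  venous_network(vessels, inputs, reference_nodes = refs)
}
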