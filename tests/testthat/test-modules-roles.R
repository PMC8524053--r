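two_triangles <- function() {
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  igraph::V(g)$domain <- "bacteria"
  structure(list(graph = g, st = 0.5, kind = "bacterial", compartment = "Non"),
    class = "co_network"
  )
}

test_that("greedy modularity splits two disjoint triangles at Q = 0.5", {
  net <- two_triangles()
  part <- detect_modules(net)
  expect_equal(length(unique(part$module)), 2)
  expect_equal(attr(part, "modularity"), 0.5)
  expect_equal(modularity_score(net, part), 0.5)
  expect_equal(glance(part)$n_modules, 2)
})

test_that("a complete graph collapses to a single module with Q = 0", {
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- paste0("n", 1:6)
  igraph::V(g)$domain <- "bacteria"
  net <- structure(list(graph = g, st = 0.5, kind = "bacterial", compartment = "Non"),
    class = "co_network"
  )
  part <- detect_modules(net)
  expect_equal(length(unique(part$module)), 1)
  expect_equal(attr(part, "modularity"), 0)
})

test_that("planted two-clique graphs are recovered exactly", {
  for (s in 1:5) {
    set.seed(s)
    k <- 20
    g <- igraph::disjoint_union(igraph::make_full_graph(k), igraph::make_full_graph(k))
    g <- igraph::add_edges(g, c(1, k + 1)) # single bridging edge
    igraph::V(g)$name <- paste0("n", 1:(2 * k))
    igraph::V(g)$domain <- "bacteria"
    net <- structure(list(graph = g, st = 0.5, kind = "bacterial", compartment = "Non"),
      class = "co_network"
    )
    part <- detect_modules(net)
    truth <- rep(1:2, each = k)
    expect_equal(nmi_of(part$module, truth), 1)
  }
})

test_that("modularity matches the formula oracle and igraph on random partitions", {
  for (s in 1:8) {
    net <- random_co_network(25, p = 0.2, seed = s)
    g <- igraph::induced_subgraph(net$graph, igraph::degree(net$graph) > 0)
    net$graph <- g
    nodes <- igraph::V(g)$name
    set.seed(s + 100)
    mem <- stats::setNames(sample(1:4, length(nodes), replace = TRUE), nodes)
    part <- tibble::tibble(node = nodes, module = unname(mem))
    q <- modularity_score(net, part)
    expect_equal(q, oracle_modularity(g, mem), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(g, factor(mem[nodes])), tolerance = 1e-12)
  }
})

test_that("modularity degenerate cases and errors behave", {
  net <- two_triangles()
  one <- tibble::tibble(node = igraph::V(net$graph)$name, module = 1)
  expect_equal(modularity_score(net, one), 0)
  # merging the triangles then exiling one node scores below the true split
  worse <- tibble::tibble(
    node = igraph::V(net$graph)$name,
    module = c(1, 1, 1, 1, 1, 2)
  )
  expect_lt(modularity_score(net, worse), 0.5)
  expect_error(modularity_score(net, one[-1, ]), "does not cover")
  expect_error(detect_modules(
    structure(
      list(
        graph = igraph::make_empty_graph(3, directed = FALSE),
        st = 0.5, kind = "bacterial", compartment = "Non"
      ),
      class = "co_network"
    )
  ), "edgeless")
})

test_that("Zi and Pi match a brute-force link-count oracle on random graphs", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:30, 1)
    net <- random_co_network(n, p = 0.25, seed = s)
    g <- igraph::induced_subgraph(net$graph, igraph::degree(net$graph) > 0)
    if (igraph::vcount(g) < 4) next
    net$graph <- g
    nodes <- igraph::V(g)$name
    mem <- stats::setNames(sample(1:3, length(nodes), replace = TRUE), nodes)
    part <- tibble::tibble(node = nodes, module = unname(mem))
    got <- zi_pi(net, part)
    want <- oracle_zipi(g, mem)
    got <- got[match(want$node, got$node), ]
    expect_equal(got$zi, want$zi, tolerance = 1e-10)
    expect_equal(got$pi, want$pi, tolerance = 1e-10)
    expect_equal(got$degree, want$degree)
    # link conservation: kappa sums checked implicitly by pi in [0, 1)
    expect_true(all(got$pi >= 0 & got$pi < 1))
  }
})

test_that("Zi standardisation has mean 0 and sd 1 within varying modules", {
  net <- random_co_network(40, p = 0.2, seed = 2)
  g <- igraph::induced_subgraph(net$graph, igraph::degree(net$graph) > 0)
  net$graph <- g
  part <- detect_modules(net)
  roles <- zi_pi(net, part)
  by_mod <- split(roles, roles$module)
  for (b in by_mod) {
    if (nrow(b) >= 2 && stats::sd(b$zi) > 0) {
      expect_equal(mean(b$zi), 0, tolerance = 1e-10)
      expect_equal(stats::sd(b$zi), 1, tolerance = 1e-10)
    }
  }
})

test_that("Pi reflects the spread of links over modules", {
  # hub with 4 links, one into each of 4 modules: Pi = 1 - 4 (1/4)^2 = 0.75
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("hub", paste0("leaf", 1:4))
  igraph::V(g)$domain <- "bacteria"
  net <- structure(list(graph = g, st = 0.5, kind = "bacterial", compartment = "Non"),
    class = "co_network"
  )
  part <- tibble::tibble(node = igraph::V(g)$name, module = c(5, 1:4))
  roles <- zi_pi(net, part)
  expect_equal(roles$pi[roles$node == "hub"], 0.75)
  # all links internal -> Pi = 0
  net2 <- two_triangles()
  part2 <- tibble::tibble(node = igraph::V(net2$graph)$name, module = rep(1:2, each = 3))
  expect_true(all(zi_pi(net2, part2)$pi == 0))
})

test_that("role classification applies the strict printed thresholds", {
  roles <- tibble::tibble(
    node = paste0("n", 1:6), domain = "bacteria", module = 1, degree = 5,
    zi = c(3.0, 1.0, 0, 3.0, 2.5, 2.6),
    pi = c(0.10, 0.70, 0, 0.70, 0.62, 0.62)
  )
  out <- classify_roles(roles)
  expect_equal(out$role, c(
    "module_hub", "connector", "peripheral",
    "network_hub", "peripheral", "module_hub"
  ))
  # total function: one role each
  expect_true(all(out$role %in% c("network_hub", "module_hub", "connector", "peripheral")))
})

test_that("keystone reports list non-peripherals with top-degree ties flagged", {
  roles <- tibble::tibble(
    node = paste0("n", 1:6), domain = c(rep("bacteria", 3), rep("fungi", 3)),
    module = 1, degree = c(9, 7, 5, 5, 3, 2),
    zi = c(3, 3, 0, 0, 0, 0), pi = c(0.1, 0.1, 0.7, 0.7, 0.7, 0.1)
  )
  ks <- keystone_report(classify_roles(roles))
  expect_equal(nrow(ks), 5) # n6 is peripheral
  expect_equal(ks$node[1:2], c("n1", "n2"))
  expect_equal(sum(ks$top_degree), 4) # tie at rank 3 (two nodes with degree 5)
  props <- attr(ks, "domain_proportions")
  expect_equal(props$proportion[props$domain == "fungi"], 2 / 5)

  # an all-peripheral network yields an empty keystone list
  none <- keystone_report(classify_roles(dplyr::mutate(roles, zi = 0, pi = 0)))
  expect_equal(nrow(none), 0)
})

test_that("module composition reports only modules above the strict size cut", {
  part <- tibble::tibble(
    node = paste0("n", 1:55),
    module = c(rep(1, 20), rep(2, 15), rep(3, 20))
  )
  doms <- stats::setNames(
    c(rep(c("bacteria", "fungi"), 10), rep("bacteria", 15), rep("fungi", 20)),
    part$node
  )
  comp <- module_composition(part, doms, min_size = 15)
  expect_equal(comp$module, c(1, 3)) # the 15-node module is excluded (strict)
  expect_equal(comp$frac_bacteria[comp$module == 1], 0.5)
  expect_equal(comp$frac_fungi[comp$module == 3], 1)
  expect_true(all(comp$frac_bacteria + comp$frac_fungi == 1))
})
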