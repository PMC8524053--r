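# Shared fixtures and independent oracles used across the suite.

# quick abund_tbl from a matrix
make_abund <- function(m, domain = NULL, compartment = "Non", mode = "counts") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("OTUB_%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("%s_%02d", compartment, seq_len(ncol(m)))
  domain <- domain %||% rep("bacteria", nrow(m))
  samples <- tibble::tibble(
    sample_id = colnames(m), compartment = compartment,
    replicate = seq_len(ncol(m))
  )
  abundance_table(m, domain, samples, mode = mode)
}

# class a plain symmetric matrix as a co_corr
make_corr <- function(m, domain = NULL) {
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- sprintf("O%03d", seq_len(nrow(m)))
  structure(m,
    domain = domain %||% rep("bacteria", nrow(m)), method = "pearson",
    class = c("co_corr", "matrix", "array")
  )
}

# random named graph wrapped as a co_network
random_co_network <- function(n, p = 0.2, seed = 1, domain = NULL) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  igraph::V(g)$domain <- domain %||% rep("bacteria", n)
  igraph::E(g)$r <- stats::runif(igraph::ecount(g), 0.6, 1)
  igraph::E(g)$sign <- "positive"
  igraph::E(g)$interdomain <- FALSE
  structure(list(graph = g, st = 0.6, kind = "BFA", compartment = NA_character_),
    class = "co_network"
  )
}

# brute-force Pearson correlation from the definition: cov / (sd * sd)
oracle_pearson <- function(x, y) {
  n <- length(x)
  cv <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cv / (sqrt(sum((x - mean(x))^2 / (n - 1))) * sqrt(sum((y - mean(y))^2 / (n - 1))))
}

# brute-force Zi/Pi by explicit per-node, per-module link counting
oracle_zipi <- function(graph, membership) {
  nodes <- igraph::V(graph)$name
  el <- igraph::as_edgelist(graph, names = TRUE)
  kappa <- function(node, mod) {
    sum((el[, 1] == node & membership[el[, 2]] == mod) |
      (el[, 2] == node & membership[el[, 1]] == mod))
  }
  mods <- sort(unique(membership))
  out <- lapply(nodes, function(v) {
    k <- sum(el[, 1] == v | el[, 2] == v)
    kis <- vapply(mods, function(s) kappa(v, s), 1)
    own <- membership[[v]]
    peers <- nodes[membership[nodes] == own]
    peer_kappa <- vapply(peers, function(u) kappa(u, own), 1)
    s <- stats::sd(peer_kappa)
    zi <- if (is.na(s) || s == 0) 0 else (kappa(v, own) - mean(peer_kappa)) / s
    pi <- if (k == 0) 0 else 1 - sum((kis / k)^2)
    data.frame(node = v, zi = zi, pi = pi, degree = k)
  })
  do.call(rbind, out)
}

# exact two-sided Fisher p by enumeration of the hypergeometric distribution
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Newman Q straight from the definition, looping over modules
oracle_modularity <- function(graph, membership) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  m <- nrow(el)
  deg <- igraph::degree(graph)
  q <- 0
  for (s in unique(membership)) {
    ls <- sum(membership[el[, 1]] == s & membership[el[, 2]] == s)
    ds <- sum(deg[names(membership)[membership == s]])
    q <- q + ls / m - (ds / (2 * m))^2
  }
  q
}

# normalised mutual information between two labelings of the same nodes
nmi_of <- function(a, b) igraph::compare(as.integer(factor(a)), as.integer(factor(b)), "nmi")

`%||%` <- function(x, y) if (is.null(x)) y else x
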