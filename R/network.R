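#' Build a co-occurrence network from a thresholded correlation matrix
#'
#' Draws an undirected edge between every OTU pair with |r| >= St, keeping
#' the signed correlation on the edge and flagging edges whose endpoints
#' belong to different domains (inter-domain edges of a bacterial-fungal
#' association network). Isolated OTUs are not part of the network.
#'
#' @param corr A `co_corr` matrix (or plain symmetric correlation matrix).
#' @param st Similarity threshold in (0, 1], typically from
#'   [select_threshold()].
#' @param domains Optional per-OTU domain labels; taken from `corr` when
#'   built by [correlation_matrix()].
#' @param kind Network kind: `"BFA"`, `"bacterial"` or `"fungal"`.
#' @param compartment Optional compartment label carried for reporting.
#' @return A `co_network`: the igraph graph (vertex attribute `domain`;
#'   edge attributes `r`, `sign`, `interdomain`) plus the St that produced
#'   it.
#' @export
build_network <- function(corr, st, domains = NULL,
                          kind = c("BFA", "bacterial", "fungal"),
                          compartment = NA_character_) {
  kind <- match.arg(kind)
  if (st <= 0 || st > 1) stop("st must lie in (0, 1]", call. = FALSE)
  a <- unclass(corr)
  domains <- domains %||% attr(corr, "domain") %||% rep("bacteria", nrow(a))
  ids <- rownames(a) %||% sprintf("OTU_%04d", seq_len(nrow(a)))
  hit <- which(abs(a) >= st & upper.tri(a), arr.ind = TRUE)
  edges <- tibble::tibble(
    from = ids[hit[, 1]], to = ids[hit[, 2]],
    r = a[hit],
    sign = ifelse(a[hit] >= 0, "positive", "negative"),
    interdomain = domains[hit[, 1]] != domains[hit[, 2]]
  )
  used <- ids %in% c(edges$from, edges$to) # degree-0 OTUs drop out
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = ids[used], domain = domains[used])
  )
  structure(list(graph = g, st = st, kind = kind, compartment = compartment),
    class = "co_network"
  )
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf(
    "<co_network> %s%s: %d nodes, %d edges (St = %.2f)\n",
    x$kind, if (is.na(x$compartment)) "" else paste0(" / ", x$compartment),
    igraph::vcount(x$graph), igraph::ecount(x$graph), x$st
  ))
  invisible(x)
}

#' Tidy a co-occurrence network into its edge list
#' @param x A `co_network`.
#' @param ... Unused.
#' @return Tibble `from`, `to`, `r`, `sign`, `interdomain`.
#' @method tidy co_network
#' @export
tidy.co_network <- function(x, ...) {
  if (igraph::ecount(x$graph) == 0) {
    return(tibble::tibble(
      from = character(), to = character(), r = double(),
      sign = character(), interdomain = logical()
    ))
  }
  tibble::as_tibble(igraph::as_data_frame(x$graph, what = "edges"))
}

# R^2 of the least-squares power-law fit to the degree-frequency histogram
# in log-log space. Two distinct degrees determine the line exactly (R^2 = 1);
# fewer leave the fit undefined.
powerlaw_r2 <- function(deg) {
  tab <- table(deg[deg > 0])
  if (length(tab) < 2) {
    return(NA_real_)
  }
  k <- log10(as.numeric(names(tab)))
  f <- log10(as.numeric(tab))
  if (stats::sd(f) == 0) {
    return(1) # flat histogram: a zero-slope line fits exactly
  }
  summary(stats::lm(f ~ k))$r.squared
}

#' Summarise network topology
#'
#' Computes the standard global descriptors: node and edge counts, average
#' connectivity avgK = 2E/N, mean local clustering coefficient (degree-1
#' nodes counted as 0), mean geodesic distance on the largest connected
#' component, and the R-squared of the least-squares power-law fit to the
#' degree-frequency histogram in log-log space.
#'
#' @param net A `co_network`.
#' @return One-row tibble: `compartment`, `kind`, `st`, `n_nodes`,
#'   `n_edges`, `avg_k`, `avg_clustering`, `avg_geodesic`, `powerlaw_r2`,
#'   `modularity` (NA until modules are detected; see [detect_modules()]).
#' @export
network_summary <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) {
    return(tibble::tibble(
      compartment = net$compartment, kind = net$kind, st = net$st,
      n_nodes = 0L, n_edges = 0L, avg_k = NA_real_, avg_clustering = NA_real_,
      avg_geodesic = NA_real_, powerlaw_r2 = NA_real_, modularity = NA_real_
    ))
  }
  clus <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  comps <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comps$membership == which.max(comps$csize)))
  geo <- if (igraph::vcount(giant) > 1) igraph::mean_distance(giant, directed = FALSE) else NA_real_
  tibble::tibble(
    compartment = net$compartment, kind = net$kind, st = net$st,
    n_nodes = n, n_edges = e, avg_k = 2 * e / n,
    avg_clustering = mean(clus), avg_geodesic = geo,
    powerlaw_r2 = powerlaw_r2(igraph::degree(g)), modularity = NA_real_
  )
}

#' Glance at a co-occurrence network
#' @param x A `co_network`.
#' @param ... Unused.
#' @return The [network_summary()] row.
#' @method glance co_network
#' @export
glance.co_network <- function(x, ...) network_summary(x)

#' Compare edge densities of two networks with Fisher's exact test
#'
#' Tests whether two networks differ in connectivity by comparing realised
#' versus possible edges: the 2x2 table is
#' \code{[[E_A, P_A - E_A], [E_B, P_B - E_B]]} with P = N(N-1)/2, evaluated
#' by a two-sided Fisher's exact test.
#'
#' @param net_a,net_b `co_network`s with at least 2 nodes each.
#' @return One-row tibble with edge/possible counts, odds ratio and p-value.
#' @export
compare_connectivity <- function(net_a, net_b) {
  na <- igraph::vcount(net_a$graph)
  nb <- igraph::vcount(net_b$graph)
  if (na < 2 || nb < 2) stop("both networks need at least 2 nodes", call. = FALSE)
  ea <- igraph::ecount(net_a$graph)
  eb <- igraph::ecount(net_b$graph)
  pa <- na * (na - 1) / 2
  pb <- nb * (nb - 1) / 2
  ft <- stats::fisher.test(matrix(c(ea, pa - ea, eb, pb - eb), 2, byrow = TRUE))
  tibble::tibble(
    edges_a = ea, possible_a = pa, edges_b = eb, possible_b = pb,
    odds_ratio = unname(ft$estimate), p_value = ft$p.value
  )
}

#' Count intra- and inter-domain edges
#'
#' @param net A `co_network` (meaningful for BFA networks; a single-domain
#'   network yields zero inter-domain edges with a warning).
#' @return One-row tibble `intra`, `inter`; the counts sum to the edge count.
#' @export
edge_domain_counts <- function(net) {
  doms <- unique(igraph::V(net$graph)$domain)
  inter <- igraph::E(net$graph)$interdomain
  if (length(doms) < 2) {
    warning("single-domain network: no inter-domain edges possible")
  }
  tibble::tibble(intra = sum(!inter), inter = sum(inter))
}

#' Export a network for external visualisation
#'
#' Writes GraphML (loadable by Cytoscape or Gephi) or a plain tab-separated
#' edge list (`from`, `to`, `r`, `sign`, `interdomain`).
#'
#' @param net A `co_network`.
#' @param path Output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    readr::write_tsv(tidy(net), path, progress = FALSE)
  }
  invisible(path)
}
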