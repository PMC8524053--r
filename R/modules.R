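#' Detect modules by greedy modularity optimisation
#'
#' Partitions the network with the Clauset-Newman-Moore agglomerative
#' greedy modularity algorithm (edges unweighted), the standard choice for
#' module detection in molecular ecological networks. A modularity above
#' 0.4 is conventionally read as evidence of modular structure (see
#' [flag_modularity()]).
#'
#' @param net A `co_network` with at least one edge.
#' @return A `module_partition`: tibble `node`, `module` with the achieved
#'   modularity in the `modularity` attribute.
#' @export
detect_modules <- function(net) {
  g <- net$graph
  if (igraph::ecount(g) == 0) stop("cannot detect modules in an edgeless network", call. = FALSE)
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  # cut the merge dendrogram at the maximal-modularity step; on ties keep
  # the coarser partition (fewer modules), so e.g. a complete graph yields
  # a single module rather than a zero-gain split
  qpath <- cl$modularity
  i_best <- max(which(qpath >= max(qpath) - 1e-12))
  k_best <- igraph::vcount(g) - i_best + 1
  mem <- suppressWarnings(igraph::cut_at(cl, no = k_best))
  part <- tibble::tibble(
    node = igraph::V(g)$name,
    module = as.integer(mem)
  )
  structure(part,
    modularity = modularity_score(net, part), method = "fast_greedy",
    class = c("module_partition", class(part))
  )
}

#' Newman modularity of a partition
#'
#' Evaluates Q = sum_s (l_s / m - (d_s / 2m)^2), where l_s is the number of
#' edges inside module s, d_s the total degree of its nodes and m the total
#' edge count.
#'
#' @param net A `co_network`.
#' @param partition A `module_partition`, or any data frame with `node` and
#'   `module` columns covering every network node.
#' @return The modularity Q (a real in \[-0.5, 1\]).
#' @export
modularity_score <- function(net, partition) {
  g <- net$graph
  part <- tibble::as_tibble(partition)
  mem <- stats::setNames(part$module, part$node)
  nodes <- igraph::V(g)$name
  uncovered <- setdiff(nodes, part$node)
  if (length(uncovered)) {
    stop("partition does not cover node(s): ", paste(utils::head(uncovered, 3), collapse = ", "),
      call. = FALSE
    )
  }
  m <- igraph::ecount(g)
  if (m == 0) stop("modularity undefined for an edgeless network", call. = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  l_s <- table(factor(mem[el[, 1]], levels = unique(mem))[mem[el[, 1]] == mem[el[, 2]]])
  deg <- igraph::degree(g)
  d_s <- tapply(deg[nodes], mem[nodes], sum)
  sum(l_s / m) - sum((d_s / (2 * m))^2)
}

#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' For each node i with degree k_i and kappa_is links into module s:
#' Zi standardises the within-own-module link count against the other
#' members of its module, Zi = (kappa_ii - mean kappa) / sd kappa (0 when
#' the standard deviation vanishes); Pi = 1 - sum_s (kappa_is / k_i)^2 is
#' the participation coefficient, 0 when all links stay inside the node's
#' own module and approaching 1 as links spread evenly over modules.
#'
#' @param net A `co_network`.
#' @param partition A `module_partition` covering every node.
#' @return Tibble `node`, `domain`, `module`, `degree`, `zi`, `pi`.
#' @export
zi_pi <- function(net, partition) {
  g <- net$graph
  part <- tibble::as_tibble(partition)
  mem <- stats::setNames(part$module, part$node)
  nodes <- igraph::V(g)$name
  if (length(setdiff(nodes, part$node))) stop("partition does not cover all nodes", call. = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  # links from each node into each module, counted from both edge endpoints
  long <- tibble::tibble(
    node = c(el[, 1], el[, 2]),
    to_module = c(mem[el[, 2]], mem[el[, 1]])
  )
  kis <- dplyr::count(long, .data$node, .data$to_module, name = "kappa")
  deg <- igraph::degree(g)
  own <- tibble::tibble(node = nodes, module = unname(mem[nodes]), degree = unname(deg[nodes]))
  kappa_own <- dplyr::left_join(own,
    dplyr::rename(kis, module = "to_module"),
    by = c("node", "module")
  )
  kappa_own$kappa[is.na(kappa_own$kappa)] <- 0L
  zi_tbl <- kappa_own |>
    dplyr::group_by(.data$module) |>
    dplyr::mutate(
      zi = {
        s <- stats::sd(.data$kappa)
        if (is.na(s) || s == 0) {
          rep(0, dplyr::n()) # module indistinguishable from its average
        } else {
          (.data$kappa - mean(.data$kappa)) / s
        }
      }
    ) |>
    dplyr::ungroup()
  pi_tbl <- kis |>
    dplyr::left_join(own[, c("node", "degree")], by = "node") |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(pi = 1 - sum((.data$kappa / .data$degree)^2))
  out <- zi_tbl |>
    dplyr::left_join(pi_tbl, by = "node") |>
    dplyr::select("node", "module", "degree", "zi", "pi")
  out$pi[is.na(out$pi)] <- 0
  dom <- stats::setNames(igraph::V(g)$domain, nodes)
  out$domain <- unname(dom[out$node])
  out[, c("node", "domain", "module", "degree", "zi", "pi")]
}

#' Classify node topological roles from Zi and Pi
#'
#' Applies the conventional thresholds: network hubs (Zi > 2.5 and
#' Pi > 0.62), module hubs (Zi > 2.5, Pi <= 0.62), connectors (Zi <= 2.5,
#' Pi > 0.62) and peripherals otherwise. Thresholds are strict, so
#' boundary-equal values fall to the less connected role.
#'
#' @param roles Tibble from [zi_pi()] (columns `zi`, `pi` required).
#' @param zi_threshold,pi_threshold Role thresholds (defaults 2.5 and 0.62).
#' @return The input with a `role` column added.
#' @export
classify_roles <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  dplyr::mutate(
    tibble::as_tibble(roles),
    role = dplyr::case_when(
      .data$zi > zi_threshold & .data$pi > pi_threshold ~ "network_hub",
      .data$zi > zi_threshold ~ "module_hub",
      .data$pi > pi_threshold ~ "connector",
      TRUE ~ "peripheral"
    )
  )
}

#' Report keystone taxa
#'
#' Keystone taxa are the non-peripheral nodes (network hubs, module hubs and
#' connectors). The report lists them by decreasing degree, flags the
#' `top_n` highest-degree keystones (ties at the boundary are all flagged),
#' and attaches per-domain keystone proportions as the `domain_proportions`
#' attribute.
#'
#' @param roles Classified roles from [classify_roles()].
#' @param taxonomy Optional tibble with columns `node` and `taxonomy` to
#'   annotate keystones.
#' @param top_n How many top-degree keystones to flag (default 3).
#' @return Tibble of keystones (`node`, `domain`, `module`, `degree`,
#'   `role`, `top_degree`, optional `taxonomy`), possibly empty.
#' @export
keystone_report <- function(roles, taxonomy = NULL, top_n = 3) {
  ks <- roles |>
    dplyr::filter(.data$role != "peripheral") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
  ks$top_degree <- dplyr::min_rank(dplyr::desc(ks$degree)) <= top_n
  if (!is.null(taxonomy)) {
    ks <- dplyr::left_join(ks, tibble::as_tibble(taxonomy), by = "node")
  }
  props <- if (nrow(ks)) {
    dplyr::count(ks, .data$domain) |>
      dplyr::mutate(proportion = .data$n / sum(.data$n))
  } else {
    tibble::tibble(domain = character(), n = integer(), proportion = double())
  }
  structure(ks, domain_proportions = props)
}

#' Per-module domain composition
#'
#' Summarises, for every module strictly larger than `min_size` nodes, how
#' many bacterial and fungal members it holds and their fractions.
#'
#' @param partition A `module_partition`.
#' @param domains Named character vector (node -> domain) or tibble with
#'   `node`, `domain` columns.
#' @param min_size Strict minimum module size (default 15: only modules
#'   with more than 15 nodes are reported).
#' @return Tibble `module`, `size`, `n_bacteria`, `n_fungi`,
#'   `frac_bacteria`, `frac_fungi`.
#' @export
module_composition <- function(partition, domains, min_size = 15) {
  part <- tibble::as_tibble(partition)
  if (is.data.frame(domains)) domains <- stats::setNames(domains$domain, domains$node)
  part$domain <- unname(domains[part$node])
  part |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      size = dplyr::n(),
      n_bacteria = sum(.data$domain == "bacteria"),
      n_fungi = sum(.data$domain == "fungi")
    ) |>
    dplyr::filter(.data$size > min_size) |>
    dplyr::mutate(
      frac_bacteria = .data$n_bacteria / .data$size,
      frac_fungi = .data$n_fungi / .data$size
    )
}

#' Tidy a module partition
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return Tibble `node`, `module`.
#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) tibble::as_tibble(x)

#' Glance at a module partition
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return One-row tibble: `n_modules`, `modularity`, `method`.
#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(
    n_modules = length(unique(x$module)),
    modularity = attr(x, "modularity"),
    method = attr(x, "method")
  )
}
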