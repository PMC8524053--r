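#' Pipeline configuration
#'
#' Collects every stage parameter of the four-compartment analysis in one
#' place: the 8-of-12 prevalence rule, the 0.01% total-abundance cut, the
#' St scan bounds, the Zi/Pi role thresholds (2.5 / 0.62), the strict
#' module-size cut (> 15 nodes), the modularity threshold (M > 0.4) and the
#' BH significance level.
#'
#' @param compartments Compartments to process (subset of Non/Rhi/Epi/Endo).
#' @param min_detected,of_replicates Prevalence rule (default 8 of 12).
#' @param abundance_min_fraction Total-abundance pre-filter, strict fraction
#'   (default 1e-4 = 0.01%; `NULL` disables it).
#' @param st_min,st_max,st_step,st_alpha,st_window Threshold-scan settings
#'   passed to [select_threshold()].
#' @param zi_threshold,pi_threshold Node-role thresholds.
#' @param module_min_size Strict module-size cut for composition reporting.
#' @param modularity_threshold Modular-structure flag threshold.
#' @param bh_alpha BH significance level for enrichment.
#' @param seed Global seed recorded in the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(compartments = COMPARTMENTS,
                       min_detected = 8, of_replicates = 12,
                       abundance_min_fraction = 1e-4,
                       st_min = 0.30, st_max = 0.99, st_step = 0.01,
                       st_alpha = 0.05, st_window = 2,
                       zi_threshold = 2.5, pi_threshold = 0.62,
                       module_min_size = 15, modularity_threshold = 0.4,
                       bh_alpha = 0.05, seed = 1) {
  bad <- setdiff(compartments, COMPARTMENTS)
  if (length(bad)) stop("unknown compartment label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(
    min_detected >= 0, of_replicates >= 3, zi_threshold > 0, pi_threshold > 0,
    module_min_size > 0, modularity_threshold > 0, bh_alpha > 0
  )
  structure(as.list(environment()), class = "run_config")
}

#' Flag modular structure
#'
#' Adds the conventional `modular` flag: modularity strictly above the
#' configured threshold (default M > 0.4) counts as modular structure.
#'
#' @param summary A summary tibble with a `modularity` column.
#' @param threshold Strict threshold (default 0.4).
#' @return The summary with a logical `modular` column.
#' @export
flag_modularity <- function(summary, threshold = 0.4) {
  dplyr::mutate(summary, modular = .data$modularity > threshold)
}

# run one network kind for one compartment: correlate, select St, build,
# partition, classify
analyse_network <- function(rel, kind, compartment, config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s/%s] stage '%s' failed: %s", compartment, kind, name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }
  corr <- stage("correlation", correlation_matrix(rel))
  scan <- stage("threshold", select_threshold(corr,
    st_min = config$st_min, st_max = config$st_max, step = config$st_step,
    alpha = config$st_alpha, window = config$st_window
  ))
  net <- stage("network", build_network(corr, scan$st, kind = kind, compartment = compartment))
  summ <- network_summary(net)
  part <- NULL
  roles <- NULL
  if (igraph::ecount(net$graph) > 0) {
    part <- stage("modules", detect_modules(net))
    summ$modularity <- attr(part, "modularity")
    roles <- stage("roles", classify_roles(zi_pi(net, part),
      zi_threshold = config$zi_threshold, pi_threshold = config$pi_threshold
    ))
  }
  list(scan = scan, network = net, summary = summ, partition = part, roles = roles)
}

#' Run the full multi-compartment network analysis
#'
#' For every configured compartment: applies the total-abundance cut and the
#' prevalence filter to each domain's counts, converts the retained OTUs to
#' relative abundances, and builds three networks (bacterial, fungal and the
#' merged-table BFA network), each with its own RMT-selected St, topology
#' summary, greedy-modularity partition, Zi-Pi role table and keystone
#' report. Results are deterministic given inputs and configuration; the
#' manifest records parameters, the seed and a checksum per output table so
#' reruns can be verified.
#'
#' @param bacteria,fungi `abund_tbl`s in counts mode covering the
#'   configured compartments.
#' @param config A [run_config()].
#' @return A `pipeline_run` list: `summaries` (one row per network, with
#'   `modular` flag), `networks`, `scans`, `partitions`, `roles`,
#'   `keystones`, `compositions`, and `manifest`.
#' @export
run_pipeline <- function(bacteria, fungi, config = run_config()) {
  comps <- config$compartments
  kinds <- c("bacterial", "fungal", "BFA")
  results <- list()
  for (cp in comps) {
    prep <- lapply(list(bacteria = bacteria, fungi = fungi), function(tab) {
      x <- filter_compartment(tab, cp)
      if (!is.null(config$abundance_min_fraction)) {
        x <- abundance_cut(x, config$abundance_min_fraction)
      }
      x <- prevalence_filter(x, config$min_detected, config$of_replicates)
      to_relative_abundance(x)
    })
    rel <- list(
      bacterial = prep$bacteria, fungal = prep$fungi,
      BFA = merge_domains(prep$bacteria, prep$fungi)
    )
    for (kd in kinds) {
      results[[paste(cp, kd, sep = ".")]] <- analyse_network(rel[[kd]], kd, cp, config)
    }
  }
  summaries <- flag_modularity(
    dplyr::bind_rows(lapply(results, `[[`, "summary")),
    config$modularity_threshold
  )
  keystones <- lapply(results, function(r) {
    if (is.null(r$roles)) NULL else keystone_report(r$roles)
  })
  compositions <- lapply(results, function(r) {
    if (is.null(r$partition)) {
      return(NULL)
    }
    doms <- stats::setNames(
      igraph::V(r$network$graph)$domain,
      igraph::V(r$network$graph)$name
    )
    module_composition(r$partition, doms, config$module_min_size)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("bfanet")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "seed")],
    st = vapply(results, function(r) r$network$st, 1),
    checksums = vapply(results, function(r) {
      rlang::hash(list(r$summary, tidy(r$network), r$roles))
    }, "")
  )
  structure(
    list(
      summaries = summaries,
      networks = lapply(results, `[[`, "network"),
      scans = lapply(results, `[[`, "scan"),
      partitions = lapply(results, `[[`, "partition"),
      roles = lapply(results, `[[`, "roles"),
      keystones = keystones,
      compositions = compositions,
      manifest = manifest
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    "<pipeline_run> %d networks across %d compartment(s)\n",
    nrow(x$summaries), length(unique(x$summaries$compartment))
  ))
  print(x$summaries)
  invisible(x)
}

#' Glance at a pipeline run
#' @param x A `pipeline_run`.
#' @param ... Unused.
#' @return The per-network summary tibble.
#' @method glance pipeline_run
#' @export
glance.pipeline_run <- function(x, ...) x$summaries

#' Write all pipeline outputs to a directory
#'
#' Emits per-network edge lists (GraphML and TSV), threshold-scan tables,
#' role tables, the combined summary table and a JSON manifest.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(run$summaries, file.path(dir, "network_summaries.tsv"), progress = FALSE)
  for (nm in names(run$networks)) {
    write_network(run$networks[[nm]], file.path(dir, paste0(nm, ".graphml")))
    write_network(run$networks[[nm]], file.path(dir, paste0(nm, ".edges.tsv")), "edgelist")
    readr::write_tsv(tidy(run$scans[[nm]]), file.path(dir, paste0(nm, ".stscan.tsv")), progress = FALSE)
    if (!is.null(run$roles[[nm]])) {
      readr::write_tsv(run$roles[[nm]], file.path(dir, paste0(nm, ".roles.tsv")), progress = FALSE)
    }
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
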