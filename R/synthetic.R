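#' Define a synthetic community scenario
#'
#' A scenario describes a compartment-structured mock community: a pool of
#' bacterial and fungal OTUs, a set of planted co-varying OTU blocks
#' (modules) with a given fungal fraction each, and the sampling model
#' (log-normal latent factors, multinomial counting at a fixed library size,
#' independent dropout). The planted module labels give every downstream
#' stage — prevalence filtering, threshold selection, network construction,
#' module detection — a known ground truth.
#'
#' The sampling model: each module m gets an independent latent factor
#' f_mr ~ N(0, 1) per replicate r; OTU i in module m has log-abundance
#' mu_i + lambda * f_mr + N(0, noise_sd), background OTUs mu_i + N(0, noise_sd).
#' Counts per replicate are multinomial on the softmax of the log-abundances
#' at `library_size` draws, so the data are compositional like relative-
#' abundance sequencing reads. Dropout then zeroes entries independently,
#' mimicking the detection limits that motivate the 8-of-12 prevalence rule.
#'
#' @param n_bacteria,n_fungi OTU pool sizes per domain.
#' @param n_replicates Biological replicates per compartment (default 12,
#'   the replication the co-occurrence networks are built on).
#' @param modules List of planted modules, each `list(size =, domain_mix =)`
#'   with `domain_mix` the fungal fraction in \[0, 1\].
#' @param corr_strength Latent-factor loading lambda (>= 0); 0 plants no
#'   correlation structure.
#' @param baseline_log_mean Per-OTU baseline log-abundance mu_i (recycled;
#'   OTU order is module members first, then background). The default
#'   (`NULL`) gives module members mu = 0 and background OTUs
#'   `background_log_mean`, so the planted blocks are minority members of a
#'   community whose bulk biomass is compositionally stable — the regime in
#'   which thresholded correlation networks are interpretable.
#' @param background_log_mean Baseline for background OTUs under the default
#'   `baseline_log_mean` (default 3).
#' @param noise_sd Residual log-scale noise (> 0).
#' @param dropout_prob Per-entry dropout probability in \[0, 1).
#' @param library_size Multinomial draw count per replicate.
#' @param seed Integer seed; all randomness flows from one generator state.
#' @return A `community_scenario` object.
#' @export
community_scenario <- function(n_bacteria = 202, n_fungi = 98, n_replicates = 12,
                               modules = list(
                                 list(size = 20, domain_mix = 0.3),
                                 list(size = 20, domain_mix = 0.3),
                                 list(size = 20, domain_mix = 0.3)
                               ),
                               corr_strength = 3, baseline_log_mean = NULL,
                               background_log_mean = 3,
                               noise_sd = 0.2, dropout_prob = 0.1,
                               library_size = 1e5, seed = 1) {
  stopifnot(
    n_bacteria >= 0, n_fungi >= 0, n_replicates >= 1,
    corr_strength >= 0, noise_sd > 0, library_size >= 0
  )
  if (dropout_prob < 0 || dropout_prob >= 1) stop("dropout_prob must be in [0, 1)", call. = FALSE)
  modules <- lapply(modules, function(m) {
    stopifnot(m$size >= 1, m$domain_mix >= 0, m$domain_mix <= 1)
    m
  })
  if (sum(vapply(modules, `[[`, 1, "size")) > n_bacteria + n_fungi) {
    stop("module sizes exceed the OTU pool", call. = FALSE)
  }
  n <- n_bacteria + n_fungi
  n_mod <- sum(vapply(modules, `[[`, 1, "size"))
  mu <- if (is.null(baseline_log_mean)) {
    c(rep(0, n_mod), rep(background_log_mean, n - n_mod)) # layout: modules first
  } else {
    rep_len(baseline_log_mean, n)
  }
  structure(
    list(
      n_bacteria = n_bacteria, n_fungi = n_fungi, n_replicates = n_replicates,
      modules = modules, corr_strength = corr_strength, baseline_log_mean = mu,
      noise_sd = noise_sd, dropout_prob = dropout_prob,
      library_size = library_size, seed = as.integer(seed)
    ),
    class = "community_scenario"
  )
}

# Deterministic module/domain layout for a scenario. Module m takes
# round(size * domain_mix) fungi and the rest bacteria, drawn in order from
# each pool; remaining pool members are unstructured background OTUs.
scenario_layout <- function(sc) {
  sizes <- vapply(sc$modules, `[[`, 1, "size")
  n_fungi_mod <- vapply(sc$modules, function(m) round(m$size * m$domain_mix), 1)
  n_bact_mod <- sizes - n_fungi_mod
  if (sum(n_bact_mod) > sc$n_bacteria) {
    over <- which(cumsum(n_bact_mod) > sc$n_bacteria)[1]
    stop("module ", over, " exhausts the bacterial OTU pool", call. = FALSE)
  }
  if (sum(n_fungi_mod) > sc$n_fungi) {
    over <- which(cumsum(n_fungi_mod) > sc$n_fungi)[1]
    stop("module ", over, " exhausts the fungal OTU pool", call. = FALSE)
  }
  module <- integer(0)
  domain <- character(0)
  for (m in seq_along(sizes)) {
    module <- c(module, rep(m, sizes[m]))
    domain <- c(domain, rep("bacteria", n_bact_mod[m]), rep("fungi", n_fungi_mod[m]))
  }
  n_bg_b <- sc$n_bacteria - sum(n_bact_mod)
  n_bg_f <- sc$n_fungi - sum(n_fungi_mod)
  module <- c(module, rep(NA_integer_, n_bg_b + n_bg_f))
  domain <- c(domain, rep("bacteria", n_bg_b), rep("fungi", n_bg_f))
  otu_id <- character(length(domain))
  otu_id[domain == "bacteria"] <- sprintf("OTUB_%04d", seq_len(sum(domain == "bacteria")))
  otu_id[domain == "fungi"] <- sprintf("OTUF_%04d", seq_len(sum(domain == "fungi")))
  tibble::tibble(otu_id = otu_id, domain = domain, module = module)
}

#' Generate a synthetic community abundance table
#'
#' Draws one compartment's OTU-by-replicate count table under the scenario's
#' latent-factor model. The same seed always yields a bitwise-identical
#' table. Module latent factors are drawn first, module 1 first, so the
#' module-1 factor is the scenario's "community gradient": with the same
#' seed, [generate_env_matrix()] reproduces it and can correlate an
#' environmental variable with it.
#'
#' @param scenario A [community_scenario()].
#' @param compartment Compartment label stamped on the samples (default "Non").
#' @return An [abundance_table()] in counts mode, with the planted module of
#'   each OTU in the `planted_modules` attribute (tibble `otu_id`, `module`;
#'   background OTUs have `NA`).
#' @export
generate_community <- function(scenario, compartment = "Non") {
  sc <- scenario
  layout <- scenario_layout(sc)
  n <- nrow(layout)
  R <- sc$n_replicates
  M <- length(sc$modules)
  set.seed(sc$seed)
  f <- matrix(0, nrow = max(M, 1), ncol = R)
  for (m in seq_len(M)) f[m, ] <- stats::rnorm(R) # module 1 = first R draws
  logab <- matrix(sc$baseline_log_mean, nrow = n, ncol = R)
  in_mod <- !is.na(layout$module)
  if (any(in_mod) && M > 0) {
    logab[in_mod, ] <- logab[in_mod, ] + sc$corr_strength * f[layout$module[in_mod], , drop = FALSE]
  }
  logab <- logab + matrix(stats::rnorm(n * R, sd = sc$noise_sd), n, R)
  counts <- matrix(0L, n, R)
  for (r in seq_len(R)) {
    p <- exp(logab[, r] - max(logab[, r]))
    counts[, r] <- stats::rmultinom(1, sc$library_size, p)
  }
  if (sc$dropout_prob > 0) {
    counts[matrix(stats::runif(n * R) < sc$dropout_prob, n, R)] <- 0L
  }
  rownames(counts) <- layout$otu_id
  colnames(counts) <- sprintf("%s_%02d", compartment, seq_len(R))
  samples <- tibble::tibble(
    sample_id = colnames(counts),
    compartment = compartment, replicate = seq_len(R)
  )
  out <- abundance_table(counts, layout$domain, samples, mode = "counts")
  attr(out, "planted_modules") <- layout[, c("otu_id", "module")]
  out
}

#' Planted module labels of a generated table
#' @param x A table from [generate_community()].
#' @return Tibble `otu_id`, `module` (NA for background OTUs).
#' @export
planted_modules <- function(x) attr(x, "planted_modules")

#' Define a synthetic gene-count scenario
#'
#' Emulates per-compartment read counts over an annotated gene catalogue:
#' reads fall on genes multinomially with probability proportional to
#' baseline_rate x length (longer genes collect more reads), and planted
#' enrichments multiply a gene's rate by `fold_change` in one target
#' compartment.
#'
#' @param genes Data frame with columns `gene`, `length_bp` (> 0) and
#'   `baseline_rate` (> 0).
#' @param enriched Optional data frame with columns `gene`, `compartment`,
#'   `fold_change` (> 1) giving planted enrichments.
#' @param depth Sequencing depth per compartment (scalar, or named vector
#'   over compartments).
#' @param compartments Compartment labels (default Non/Rhi/Epi/Endo).
#' @param seed Integer seed.
#' @return A `gene_scenario` object.
#' @export
gene_scenario <- function(genes, enriched = NULL, depth = 1e5,
                          compartments = COMPARTMENTS, seed = 1) {
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("gene", "length_bp", "baseline_rate") %in% names(genes)))
  if (anyDuplicated(genes$gene)) {
    stop("duplicate gene name: ", genes$gene[duplicated(genes$gene)][1], call. = FALSE)
  }
  if (any(genes$length_bp <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (any(genes$baseline_rate < 0)) stop("baseline rates must be nonnegative", call. = FALSE)
  if (!is.null(enriched)) {
    enriched <- tibble::as_tibble(enriched)
    stopifnot(all(c("gene", "compartment", "fold_change") %in% names(enriched)))
    if (any(enriched$fold_change <= 1)) stop("planted fold_change must be > 1", call. = FALSE)
    if (!all(enriched$gene %in% genes$gene)) stop("enriched gene not in catalogue", call. = FALSE)
    if (!all(enriched$compartment %in% compartments)) stop("unknown enrichment compartment", call. = FALSE)
  }
  if (is.null(names(depth))) depth <- stats::setNames(rep_len(depth, length(compartments)), compartments)
  structure(
    list(
      genes = genes, enriched = enriched, depth = depth,
      compartments = compartments, seed = as.integer(seed)
    ),
    class = "gene_scenario"
  )
}

#' Generate a synthetic gene-count table
#'
#' @param scenario A [gene_scenario()].
#' @return Tibble with `gene`, `length_bp` and one integer count column per
#'   compartment.
#' @export
generate_gene_counts <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  base <- sc$genes$baseline_rate * sc$genes$length_bp
  counts <- sapply(sc$compartments, function(cp) {
    rate <- base
    if (!is.null(sc$enriched)) {
      hit <- sc$enriched[sc$enriched$compartment == cp, ]
      idx <- match(hit$gene, sc$genes$gene)
      rate[idx] <- rate[idx] * hit$fold_change
    }
    d <- sc$depth[[cp]]
    if (d == 0 || sum(rate) == 0) {
      integer(nrow(sc$genes))
    } else {
      as.integer(stats::rmultinom(1, d, rate / sum(rate)))
    }
  })
  out <- tibble::tibble(gene = sc$genes$gene, length_bp = sc$genes$length_bp)
  dplyr::bind_cols(out, tibble::as_tibble(counts, .name_repair = "minimal"))
}

#' Generate a synthetic environmental-variable table
#'
#' Produces the soil chemistry panel measured alongside the communities
#' (pH, salinity, oxidation-reduction potential, moisture, total C/N,
#' ammonium-, nitrate- and nitrite-N). Each variable is a linear response to
#' the community gradient plus independent noise: at `gradient_corr = g`,
#' the first variable correlates with the gradient at about g, and at g = 1
#' the whole panel is a noise-free function of it. The gradient equals the
#' module-1 latent factor drawn by [generate_community()] under the same
#' seed, so community and environment tables generated with one seed share
#' structure.
#'
#' @param n_samples Number of samples (>= 3).
#' @param gradient_corr Target correlation with the community gradient, in
#'   \[-1, 1\].
#' @param seed Integer seed.
#' @return Tibble with `sample_id` and nine environmental variables.
#' @export
generate_env_matrix <- function(n_samples, gradient_corr = 0, seed = 1) {
  if (n_samples < 3) stop("need at least 3 samples", call. = FALSE)
  if (abs(gradient_corr) > 1) stop("gradient_corr must lie in [-1, 1]", call. = FALSE)
  g <- gradient_corr
  vars <- c("pH", "salinity", "ORP", "moisture", "TC", "TN", "NH4", "NO3", "NO2")
  centre <- c(7.5, 15, -100, 40, 20000, 1500, 30, 5, 0.8)
  spread <- c(0.5, 5, 80, 10, 5000, 400, 10, 2, 0.3)
  loading <- c(1, -1, 1, 1, -1, 1, -1, 1, -1)
  set.seed(seed)
  grad <- stats::rnorm(n_samples) # same draws as the module-1 factor
  z <- g * outer(grad, loading) +
    sqrt(1 - g^2) * matrix(stats::rnorm(n_samples * length(vars)), n_samples)
  vals <- sweep(sweep(z, 2, spread, "*"), 2, centre, "+")
  colnames(vals) <- vars
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S_%02d", seq_len(n_samples))),
    tibble::as_tibble(vals)
  )
}
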