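test_that("community generation is deterministic and respects the counting model", {
  sc <- community_scenario(
    n_bacteria = 30, n_fungi = 15, library_size = 5000,
    modules = list(list(size = 10, domain_mix = 0.4)), dropout_prob = 0, seed = 7
  )
  t1 <- generate_community(sc)
  t2 <- generate_community(sc)
  expect_identical(abundance_matrix(t1), abundance_matrix(t2))
  # column sums equal the library size before dropout
  expect_true(all(colSums(abundance_matrix(t1)) == 5000))
  expect_equal(nrow(t1), 45)
  expect_equal(ncol(abundance_matrix(t1)), 12)
  expect_true(all(abundance_matrix(t1) == floor(abundance_matrix(t1))))
  # planted module fungal fraction tracks domain_mix
  lay <- dplyr::left_join(planted_modules(t1), tibble::as_tibble(t1)[, c("otu_id", "domain")],
    by = "otu_id"
  )
  m1 <- lay[!is.na(lay$module), ]
  expect_equal(mean(m1$domain == "fungi"), 0.4)
  # a different seed changes the table
  sc$seed <- 8L
  expect_false(identical(abundance_matrix(generate_community(sc)), abundance_matrix(t1)))
})

test_that("module sizes beyond the OTU pool fail naming the module", {
  expect_error(
    generate_community(community_scenario(
      n_bacteria = 10, n_fungi = 10,
      modules = list(list(size = 10, domain_mix = 0.5), list(size = 10, domain_mix = 1))
    )),
    "module 2"
  )
  expect_error(
    community_scenario(
      n_bacteria = 5, n_fungi = 5,
      modules = list(list(size = 20, domain_mix = 0.5))
    ),
    "exceed"
  )
})

test_that("no planted structure leaves pairwise correlations at the null scale", {
  # lambda = 0, no dropout: mean |r| should sit near the 12-replicate null
  # scale sqrt(2/pi)/sqrt(11) ~ 0.24, far below planted-block levels
  mean_abs <- vapply(1:50, function(s) {
    sc <- community_scenario(
      n_bacteria = 20, n_fungi = 10, corr_strength = 0,
      dropout_prob = 0, library_size = 2e4, seed = s,
      modules = list(list(size = 10, domain_mix = 0.3))
    )
    cc <- correlation_matrix(generate_community(sc))
    mean(abs(cc[upper.tri(cc)]))
  }, 1)
  expect_lt(mean(mean_abs), 0.3)
  expect_gt(mean(mean_abs), 0.1)
})

test_that("planted modules correlate internally more than across modules", {
  ok <- vapply(1:50, function(s) {
    sc <- community_scenario(
      n_bacteria = 30, n_fungi = 10, corr_strength = 3, noise_sd = 0.2,
      dropout_prob = 0, library_size = 2e4, seed = s,
      modules = list(list(size = 10, domain_mix = 0.2), list(size = 10, domain_mix = 0.2))
    )
    tab <- generate_community(sc)
    cc <- correlation_matrix(to_relative_abundance(tab))
    mod <- stats::setNames(planted_modules(tab)$module, planted_modules(tab)$otu_id)[rownames(cc)]
    ut <- upper.tri(cc)
    same <- outer(mod, mod, "==")
    same[is.na(same)] <- FALSE
    both <- outer(!is.na(mod), !is.na(mod), "&")
    mean(cc[same & ut]) > mean(cc[both & !same & ut])
  }, TRUE)
  expect_true(all(ok))
})

test_that("gene-count generation is deterministic with planted fold changes realised", {
  genes <- tibble::tibble(
    gene = paste0("g", 1:8), length_bp = rep(c(500, 1500), 4),
    baseline_rate = 1
  )
  sc <- gene_scenario(genes,
    enriched = tibble::tibble(gene = "g3", compartment = "Endo", fold_change = 8),
    depth = 1e5, seed = 3
  )
  x1 <- generate_gene_counts(sc)
  expect_identical(x1, generate_gene_counts(sc))
  expect_true(all(as.matrix(x1[, c("Non", "Rhi", "Epi", "Endo")]) >= 0))
  # planted 8-fold gene dominates its peripheral counts in every seed tried
  wins <- vapply(1:100, function(s) {
    sc$seed <- s
    x <- generate_gene_counts(sc)
    g3 <- x[x$gene == "g3", ]
    all(g3$Endo > c(g3$Non, g3$Rhi, g3$Epi))
  }, TRUE)
  expect_gte(mean(wins), 0.99)
  # realised enrichment ratio matches the compositional closed form:
  # fold / (1 + share * (fold - 1)), share = the gene's baseline read share
  x <- generate_gene_counts(gene_scenario(genes,
    enriched = tibble::tibble(gene = "g3", compartment = "Endo", fold_change = 8),
    depth = 1e6, seed = 11
  ))
  g3 <- x[x$gene == "g3", ]
  share <- 500 / sum(genes$length_bp)
  expect_equal(g3$Endo / mean(c(g3$Non, g3$Rhi, g3$Epi)),
    8 / (1 + share * 7),
    tolerance = 0.1
  )
  # with a large catalogue the share is negligible and the raw fold emerges
  big <- tibble::tibble(gene = paste0("h", 1:200), length_bp = 1000, baseline_rate = 1)
  xb <- generate_gene_counts(gene_scenario(big,
    enriched = tibble::tibble(gene = "h7", compartment = "Endo", fold_change = 8),
    depth = 2e6, seed = 12
  ))
  h7 <- xb[xb$gene == "h7", ]
  expect_equal(h7$Endo / mean(c(h7$Non, h7$Rhi, h7$Epi)), 8, tolerance = 0.1)
})

test_that("gene-count edge cases error or degenerate cleanly", {
  genes <- tibble::tibble(gene = c("a", "b"), length_bp = c(100, 100), baseline_rate = 1)
  expect_error(
    gene_scenario(tibble::tibble(
      gene = c("a", "a"), length_bp = c(1, 1),
      baseline_rate = 1
    )),
    "duplicate gene"
  )
  expect_error(
    gene_scenario(tibble::tibble(gene = "a", length_bp = 0, baseline_rate = 1)),
    "positive"
  )
  expect_error(
    gene_scenario(genes, enriched = tibble::tibble(
      gene = "a", compartment = "Endo",
      fold_change = 1
    )),
    "fold_change"
  )
  z <- generate_gene_counts(gene_scenario(genes, depth = 0, seed = 1))
  expect_true(all(as.matrix(z[, c("Non", "Rhi", "Epi", "Endo")]) == 0))
})

test_that("unenriched gene counts differ between compartments only stochastically", {
  genes <- tibble::tibble(gene = paste0("g", 1:10), length_bp = 1000, baseline_rate = 1)
  pvals <- vapply(1:60, function(s) {
    x <- generate_gene_counts(gene_scenario(genes, depth = 1e4, seed = s))
    cnt <- as.numeric(x[sample(10, 1), c("Non", "Rhi", "Epi", "Endo")])
    suppressWarnings(stats::chisq.test(cnt, p = rep(1 / 4, 4))$p.value)
  }, 1)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("environment tables are deterministic, validated and gradient-linked", {
  e1 <- generate_env_matrix(12, gradient_corr = 0.5, seed = 4)
  expect_identical(e1, generate_env_matrix(12, gradient_corr = 0.5, seed = 4))
  expect_equal(dim(e1), c(12, 10))
  expect_true(all(vapply(e1[, -1], stats::sd, 1) > 0)) # z-scorable
  expect_error(generate_env_matrix(12, gradient_corr = 1.2), "gradient_corr")
  expect_error(generate_env_matrix(2, gradient_corr = 0), "3 samples")
  # first variable tracks the community gradient (module-1 latent factor)
  cors <- vapply(1:40, function(s) {
    set.seed(s)
    grad <- stats::rnorm(30) # first draws under this seed = the gradient
    env <- generate_env_matrix(30, gradient_corr = 0.9, seed = s)
    stats::cor(env$pH, grad)
  }, 1)
  expect_equal(mean(cors), 0.9, tolerance = 0.05)
})
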