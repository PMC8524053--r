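#' Bray-Curtis dissimilarity between samples
#'
#' BC(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk) over OTUs k,
#' computed between the sample columns of an abundance table.
#'
#' @param x An `abund_tbl` with at least 2 samples (or an OTU-by-sample
#'   matrix).
#' @return A `dist` object with `method = "bray"`.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "abund_tbl")) abundance_matrix(x) else as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(m < 0)) stop("abundances must be nonnegative", call. = FALSE)
  zero <- colSums(m) == 0
  if (sum(zero) >= 2) {
    stop("Bray-Curtis undefined between all-zero samples: ",
      paste(colnames(m)[zero], collapse = ", "),
      call. = FALSE
    )
  }
  vegan::vegdist(t(m), method = "bray")
}

#' Standardised Euclidean distance between environment samples
#'
#' Z-scores every variable (sd over n - 1) and takes Euclidean distances
#' between samples. Constant variables carry no distance information and
#' are dropped with a warning.
#'
#' @param env Data frame with an optional `sample_id` column and numeric
#'   environmental variables.
#' @param standardize Z-score variables first (default TRUE).
#' @return A `dist` object labelled by sample id.
#' @export
euclidean_env <- function(env, standardize = TRUE) {
  env <- tibble::as_tibble(env)
  ids <- if ("sample_id" %in% names(env)) env$sample_id else as.character(seq_len(nrow(env)))
  num <- as.matrix(env[, vapply(env, is.numeric, TRUE), drop = FALSE])
  sds <- apply(num, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant variable(s) dropped: ", paste(colnames(num)[sds == 0], collapse = ", "))
    num <- num[, sds > 0, drop = FALSE]
  }
  if (!ncol(num)) stop("no non-constant numeric variables", call. = FALSE)
  if (standardize) num <- scale(num)
  rownames(num) <- ids
  stats::dist(num)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation r of the upper-triangle entries, with a one-sided
#' permutation p-value, p = (1 + #\{permuted r >= observed r\}) /
#' (1 + n_perm), permuting rows and columns of the second matrix
#' simultaneously (the standard positive-association alternative in
#' microbial ecology).
#'
#' @param d_a,d_b `dist` objects or symmetric matrices over the same
#'   samples (matching labels, if present).
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @return One-row tibble `statistic` (r), `p_value`, `n_perm`, `n_samples`.
#' @export
mantel_test <- function(d_a, d_b, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("use at least 99 permutations", call. = FALSE)
  ma <- as.matrix(d_a)
  mb <- as.matrix(d_b)
  if (!identical(dim(ma), dim(mb))) stop("distance matrices differ in size", call. = FALSE)
  la <- rownames(ma)
  lb <- rownames(mb)
  if (!is.null(la) && !is.null(lb)) {
    if (!setequal(la, lb)) {
      stop("sample sets differ: ", paste(utils::head(setdiff(union(la, lb), intersect(la, lb)), 3),
        collapse = ", "
      ), call. = FALSE)
    }
    mb <- mb[la, la] # align on the first matrix's ordering
  }
  n <- nrow(ma)
  ut <- upper.tri(ma)
  va <- ma[ut]
  r_obs <- stats::cor(va, mb[ut])
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    if (stats::cor(va, mb[p, p][ut]) >= r_obs) hits <- hits + 1L
  }
  tibble::tibble(
    statistic = r_obs, p_value = (1 + hits) / (1 + n_perm),
    n_perm = as.integer(n_perm), n_samples = n
  )
}
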