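#' Pearson correlation matrix across replicates
#'
#' Correlates every OTU pair across the replicate samples of one
#' compartment; this similarity matrix is the input to random-matrix-theory
#' threshold selection and network construction. Constant rows carry no
#' correlation signal and are dropped with a warning.
#'
#' @param x An `abund_tbl` (relative abundances by convention, but any mode
#'   is accepted) with at least 3 samples and 2 OTUs.
#' @param method Correlation type: `"pearson"` (default) or `"spearman"`.
#' @return A symmetric correlation matrix of class `co_corr` with unit
#'   diagonal; per-OTU domain labels travel in the `domain` attribute and
#'   the correlation type in `method`.
#' @export
correlation_matrix <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- abundance_matrix(x)
  if (ncol(m) < 3) stop("need at least 3 samples to correlate", call. = FALSE)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant OTU row(s) dropped before correlation")
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("need at least 2 non-constant OTUs", call. = FALSE)
  cc <- stats::cor(t(m), method = method)
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  dom <- stats::setNames(x$domain, x$otu_id)[rownames(cc)]
  structure(cc, domain = unname(dom), method = method, class = c("co_corr", "matrix", "array"))
}

# threshold a correlation matrix: zero sub-threshold entries, keep diagonal
threshold_corr <- function(corr, st) {
  a <- unclass(corr)
  a[abs(a) < st] <- 0
  diag(a) <- 1
  a
}

#' Unfold an eigenvalue spectrum
#'
#' Maps sorted eigenvalues onto a scale where the mean nearest-neighbour
#' spacing is 1, by passing a smooth monotone (Hyman-filtered cubic) spline
#' through a subset of the empirical cumulative spectral staircase and
#' reading off fitted positions. Unfolding removes the local density scale
#' so spacing statistics can be compared with the Poisson and
#' Gaussian-orthogonal-ensemble (GOE) limits; a local monotone fit stays
#' faithful when the spectrum carries gaps and outlying eigenvalues, as
#' thresholded correlation matrices with block structure do.
#'
#' @param eigenvalues Numeric vector of at least 20 eigenvalues.
#' @param nknots Number of staircase knots the spline passes through
#'   (default 20).
#' @param edge_trim Fraction of eigenvalues discarded at each spectral edge
#'   before fitting (default 0.01): the smooth approximation of the
#'   cumulative spectral function is least reliable where the spectral
#'   density vanishes.
#' @return Nondecreasing numeric vector of unfolded eigenvalues, in
#'   ascending spectral order.
#' @export
unfold_spectrum <- function(eigenvalues, nknots = 20, edge_trim = 0.01) {
  ev <- sort(eigenvalues)
  k <- floor(edge_trim * length(ev))
  if (k > 0) ev <- ev[(k + 1):(length(ev) - k)]
  n <- length(ev)
  if (n < 20) stop("need at least 20 eigenvalues for a reliable unfolding", call. = FALSE)
  evu <- unique(ev)
  if (length(evu) < 2) stop("degenerate spectrum: all eigenvalues equal", call. = FALSE)
  cum <- findInterval(evu, ev) # cumulative count at each distinct value
  idx <- unique(round(seq(1, length(evu), length.out = min(nknots, length(evu)))))
  f <- if (length(idx) >= 4) {
    stats::splinefun(evu[idx], cum[idx], method = "hyman")
  } else {
    stats::approxfun(evu[idx], cum[idx], rule = 2)
  }
  cummax(f(ev)) # enforce a monotone map
}

#' Goodness of fit of a spacing distribution to an RMT limit
#'
#' Chi-square test of nearest-neighbour spacings against the Poisson law
#' P(d) = exp(-d) (uncorrelated, modular spectra) or the Wigner surmise
#' P(d) = (pi d / 2) exp(-pi d^2 / 4) for the GOE (noise-dominated spectra),
#' using equal-probability bins under the null model.
#'
#' @param spacings Nonnegative spacings (>= 20 values).
#' @param model `"poisson"` or `"goe"`.
#' @param bins Target number of equal-probability bins (default 10; reduced
#'   so every bin keeps an expected count of at least 2).
#' @return One-row tibble: `model`, `statistic`, `df`, `p_value`.
#' @export
nnsd_gof <- function(spacings, model = c("poisson", "goe"), bins = 10) {
  model <- match.arg(model)
  d <- spacings
  if (length(d) < 20) stop("need at least 20 spacings", call. = FALSE)
  if (any(d < 0)) stop("spacings must be nonnegative", call. = FALSE)
  nb <- max(3, min(bins, floor(length(d) / 2)))
  qfun <- switch(model,
    poisson = function(p) -log1p(-p),
    goe = function(p) sqrt(-4 * log1p(-p) / pi)
  )
  edges <- c(-Inf, qfun(seq_len(nb - 1) / nb), Inf)
  obs <- tabulate(findInterval(d, edges, left.open = TRUE), nbins = nb)
  expd <- rep(length(d) / nb, nb)
  stat <- sum((obs - expd)^2 / expd)
  df <- nb - 1
  tibble::tibble(
    model = model, statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Select the similarity threshold by random matrix theory
#'
#' Scans candidate thresholds St over a grid; at each candidate the
#' correlation matrix is sparsified (entries with |r| < St zeroed, diagonal
#' kept), eigen-decomposed, its distinct eigenvalues unfolded, and the
#' nearest-neighbour spacing distribution tested against the Poisson law.
#' Random-matrix theory predicts GOE (Wigner) spacings while the matrix is
#' dominated by noise and a transition to Poisson spacings once only
#' system-specific (modular) correlation structure remains; the selected St
#' is the smallest candidate at which Poisson is not rejected (p > alpha)
#' for `window` consecutive candidates, which makes the choice robust to
#' single-grid-point flukes.
#'
#' @param corr A `co_corr` correlation matrix.
#' @param st_min,st_max,step Scan grid (defaults 0.30 to 0.99 by 0.01).
#' @param alpha Poisson-fit acceptance level (default 0.05).
#' @param window Number of consecutive accepting candidates required
#'   (default 2).
#' @param min_eigen Minimum number of distinct eigenvalues required to
#'   evaluate a candidate (default 20); candidates below it are infeasible.
#' @param nknots Candidate knot counts for [unfold_spectrum()]. The
#'   unfolding resolution is a nuisance choice, so each null model keeps its
#'   best fit across these resolutions: a model counts as rejected only
#'   when every unfolding rejects it.
#' @return A `threshold_scan` object: the selected `st` plus the full
#'   per-candidate audit table (`tidy()` it, or `autoplot()` it).
#' @export
select_threshold <- function(corr, st_min = 0.30, st_max = 0.99, step = 0.01,
                             alpha = 0.05, window = 2, min_eigen = 20,
                             nknots = c(20, 25, 30)) {
  candidates <- seq(st_min, st_max, by = step)
  rows <- lapply(candidates, function(st) {
    a <- threshold_corr(corr, st)
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    ev <- sort(ev)
    keep <- c(TRUE, diff(ev) > 1e-8) # duplicated eigenvalues carry no spacing signal
    ev <- ev[keep]
    n_kept <- length(ev) - 2 * floor(0.01 * length(ev)) # after edge trim
    if (n_kept - 1 < min_eigen) { # need >= min_eigen spacings
      return(tibble::tibble(
        st = st, n_eigen = length(ev), feasible = FALSE,
        chi2_poisson = NA_real_, p_poisson = NA_real_,
        chi2_goe = NA_real_, p_goe = NA_real_
      ))
    }
    fits <- lapply(nknots, function(nk) {
      sp <- diff(unfold_spectrum(ev, nknots = nk))
      rbind(nnsd_gof(sp, "poisson"), nnsd_gof(sp, "goe"))
    })
    po <- dplyr::bind_rows(lapply(fits, function(f) f[1, ]))
    go <- dplyr::bind_rows(lapply(fits, function(f) f[2, ]))
    tibble::tibble(
      st = st, n_eigen = length(ev), feasible = TRUE,
      chi2_poisson = po$statistic[which.max(po$p_value)],
      p_poisson = max(po$p_value),
      chi2_goe = go$statistic[which.max(go$p_value)],
      p_goe = max(go$p_value)
    )
  })
  scan <- dplyr::bind_rows(rows)
  ok <- !is.na(scan$p_poisson) & scan$p_poisson > alpha
  sel <- NA_real_
  for (i in seq_len(nrow(scan) - window + 1)) {
    if (all(ok[i:(i + window - 1)])) {
      sel <- scan$st[i]
      break
    }
  }
  if (is.na(sel)) {
    stop("no candidate threshold reached a Poisson-consistent spacing ",
      "distribution; widen the scan range or inspect the spectrum",
      call. = FALSE
    )
  }
  scan$selected <- scan$st == sel
  structure(list(scan = scan, st = sel, alpha = alpha, window = window),
    class = "threshold_scan"
  )
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf(
    "<threshold_scan> selected St = %.2f (alpha = %g, window = %d, %d candidates)\n",
    x$st, x$alpha, x$window, nrow(x$scan)
  ))
  invisible(x)
}

#' Tidy a threshold scan
#' @param x A `threshold_scan`.
#' @param ... Unused.
#' @return The per-candidate scan tibble (st, eigenvalue count, chi-square
#'   and p for both null models, feasibility and selection flags).
#' @method tidy threshold_scan
#' @export
tidy.threshold_scan <- function(x, ...) x$scan

#' Glance at a threshold scan
#' @param x A `threshold_scan`.
#' @param ... Unused.
#' @return One-row tibble with the selected St and scan settings.
#' @method glance threshold_scan
#' @export
glance.threshold_scan <- function(x, ...) {
  tibble::tibble(
    st = x$st, alpha = x$alpha, window = x$window,
    n_candidates = nrow(x$scan), n_feasible = sum(x$scan$feasible)
  )
}
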