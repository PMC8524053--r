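#' Load a gene-panel definition
#'
#' Panels are tab-separated files with columns `panel`, `gene`, `subgroup`
#' (and optionally `product`); the quorum-sensing and cobamide panels ship
#' with the package and can be edited or extended without code changes.
#'
#' @param path Path to a panel file; default loads both bundled panels.
#' @return Tibble `panel`, `gene`, `subgroup`, `product`.
#' @export
load_panel <- function(path = NULL) {
  paths <- path %||% c(
    system.file("extdata", "qs_panels.tsv", package = "bfanet"),
    system.file("extdata", "cobamide_panel.tsv", package = "bfanet")
  )
  out <- dplyr::bind_rows(lapply(paths, readr::read_tsv,
    show_col_types = FALSE, progress = FALSE
  ))
  dup <- out |>
    dplyr::count(.data$panel, .data$gene) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) stop("duplicate gene within panel: ", dup$gene[1], call. = FALSE)
  out
}

#' Quorum-sensing gene panels (modules 1 and 2)
#' @return Tibble of the two QS panels: module 1 (cqsA, tdh, luxR) and
#'   module 2 (lasI, rhlI, pqsH, lasR).
#' @export
qs_panels <- function() {
  load_panel(system.file("extdata", "qs_panels.tsv", package = "bfanet"))
}

#' Cobamide biosynthesis gene panel
#' @return Tibble of 15 cobamide biosynthesis genes tagged by pathway step,
#'   including aerobic (cobG, cobF, cobA) and anaerobic (cbiT, cbiE)
#'   corrin-ring adenosylation routes.
#' @export
cobamide_panel <- function() {
  load_panel(system.file("extdata", "cobamide_panel.tsv", package = "bfanet"))
}

#' Normalise gene read counts to transcripts per million (TPM)
#'
#' TPM_g = (c_g / L_g) / sum_h (c_h / L_h) x 10^6 per sample column, so
#' every column sums to one million.
#'
#' @param counts Data frame with a `gene` column, a `length_bp` column (or
#'   lengths supplied separately) and one numeric count column per sample.
#' @param lengths Optional numeric vector of gene lengths in bp (one per
#'   row), used when `counts` has no `length_bp` column.
#' @return Tibble with `gene` and one TPM column per sample.
#' @export
tpm_normalize <- function(counts, lengths = NULL) {
  counts <- tibble::as_tibble(counts)
  stopifnot("gene" %in% names(counts))
  lengths <- lengths %||% counts$length_bp
  if (is.null(lengths)) stop("gene lengths required (column `length_bp` or `lengths`)", call. = FALSE)
  if (any(lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  value_cols <- setdiff(names(counts), c("gene", "length_bp"))
  m <- as.matrix(counts[, value_cols])
  if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
  rate <- m / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    stop("all-zero sample column(s): ", paste(value_cols[tot == 0], collapse = ", "),
      call. = FALSE
    )
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  dplyr::bind_cols(
    tibble::tibble(gene = counts$gene),
    tibble::as_tibble(tpm, .name_repair = "minimal")
  )
}

#' Profile a gene panel across compartments
#'
#' Restricts a TPM table to the members of one or more panels, in long
#' format ready for heatmap display. Genes with zero TPM in a compartment
#' are flagged undetected (TPM is zero exactly when the read count is
#' zero); panel genes missing from the table entirely are kept with
#' `present = FALSE` rather than raising an error.
#'
#' @param tpm TPM tibble from [tpm_normalize()].
#' @param panel Panel tibble (default: both bundled panels).
#' @return Long tibble `panel`, `gene`, `subgroup`, `compartment`, `tpm`,
#'   `detected`, `present`.
#' @export
panel_profile <- function(tpm, panel = load_panel()) {
  tpm <- tibble::as_tibble(tpm)
  long <- tidyr::pivot_longer(tpm, -"gene",
    names_to = "compartment", values_to = "tpm"
  )
  out <- panel |>
    dplyr::select("panel", "gene", "subgroup") |>
    tidyr::crossing(compartment = unique(long$compartment)) |>
    dplyr::left_join(long, by = c("gene", "compartment")) |>
    dplyr::mutate(
      present = !is.na(.data$tpm),
      detected = .data$present & .data$tpm > 0
    )
  out$tpm[!out$present] <- NA_real_
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
#'
#' @param p P-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Pairwise between-compartment enrichment of panel genes
#'
#' For every gene and every pair of compartments, builds the 2x2 table
#' \code{[[c_A, T_A - c_A], [c_B, T_B - c_B]]} of reads on the gene versus
#' all other reads and applies a two-sided Fisher's exact test (odds-ratio
#' confidence interval reported at the 99% level). P-values are
#' Benjamini-Hochberg corrected across genes within each compartment pair;
#' q < `alpha` flags significance. Tests run on raw read counts — TPM is a
#' display scale only, Fisher's test needs counts.
#'
#' @param counts Data frame with `gene` plus one count column per
#'   compartment (a `length_bp` column is ignored).
#' @param totals Named vector of per-compartment read totals (default: the
#'   column sums, i.e. all catalogued reads).
#' @param panel Optional panel tibble; restricts testing to panel members.
#' @param alpha Significance level on q (default 0.05).
#' @param conf_level Confidence level for the reported odds-ratio interval
#'   (default 0.99).
#' @return Tibble: `gene`, `comp_a`, `comp_b`, counts and totals, `odds_ratio`,
#'   `conf_lo`, `conf_hi`, `p_value`, `q_value`, `significant`.
#' @export
pairwise_enrichment <- function(counts, totals = NULL, panel = NULL,
                                alpha = 0.05, conf_level = 0.99) {
  counts <- tibble::as_tibble(counts)
  comp_cols <- setdiff(names(counts), c("gene", "length_bp"))
  m <- as.matrix(counts[, comp_cols])
  rownames(m) <- counts$gene
  totals <- totals %||% colSums(m)
  if (any(sweep(m, 2, totals[comp_cols], "-") > 0)) {
    stop("gene count exceeds its compartment total", call. = FALSE)
  }
  if (!is.null(panel)) m <- m[rownames(m) %in% panel$gene, , drop = FALSE]
  pairs <- utils::combn(comp_cols, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]
    b <- pr[2]
    per_gene <- purrr::map_dfr(rownames(m), function(gn) {
      ca <- m[gn, a]
      cb <- m[gn, b]
      ft <- stats::fisher.test(
        matrix(c(ca, totals[[a]] - ca, cb, totals[[b]] - cb), 2, byrow = TRUE),
        conf.level = conf_level
      )
      tibble::tibble(
        gene = gn, comp_a = a, comp_b = b,
        count_a = ca, count_b = cb,
        total_a = totals[[a]], total_b = totals[[b]],
        odds_ratio = unname(ft$estimate),
        conf_lo = ft$conf.int[1], conf_hi = ft$conf.int[2],
        p_value = ft$p.value
      )
    })
    per_gene$q_value <- bh_adjust(per_gene$p_value) # BH family: one compartment pair
    per_gene
  })
  res$significant <- res$q_value < alpha
  res
}

#' Taxonomic detection frequency of panel genes
#'
#' From per-record family assignments of panel-gene reads, computes the
#' fraction of records assigned to each family within every compartment,
#' keeps the `top_k` families by overall frequency and pools the rest into
#' `"other"` (records without a family assignment are reported as
#' `"unassigned"`).
#'
#' @param gene_taxonomy Tibble with columns `family` and `compartment`, one
#'   row per annotated record; an optional `gene` column allows panel
#'   filtering.
#' @param panel Optional panel tibble to restrict records to.
#' @param top_k Number of named families to keep (default 10).
#' @return Tibble `family`, `compartment`, `n`, `frequency`; frequencies
#'   within a compartment sum to 1 across all rows.
#' @export
detection_frequency <- function(gene_taxonomy, panel = NULL, top_k = 10) {
  tax <- tibble::as_tibble(gene_taxonomy)
  if (!is.null(panel) && "gene" %in% names(tax)) {
    tax <- dplyr::filter(tax, .data$gene %in% panel$gene)
  }
  if (!nrow(tax)) stop("no taxonomy records to summarise", call. = FALSE)
  tax$family[is.na(tax$family)] <- "unassigned"
  top <- tax |>
    dplyr::filter(.data$family != "unassigned") |>
    dplyr::count(.data$family, sort = TRUE) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::pull(.data$family)
  tax$family <- dplyr::case_when(
    tax$family %in% c(top, "unassigned") ~ tax$family,
    TRUE ~ "other"
  )
  tax |>
    dplyr::count(.data$compartment, .data$family) |>
    dplyr::group_by(.data$compartment) |>
    dplyr::mutate(frequency = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("family", "compartment", "n", "frequency")
}
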