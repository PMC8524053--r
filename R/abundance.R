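#' @importFrom rlang %||% .data
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

COMPARTMENTS <- c("Non", "Rhi", "Epi", "Endo")
DOMAINS <- c("bacteria", "fungi")

#' Construct an OTU abundance table
#'
#' An `abund_tbl` couples an OTU-by-sample value matrix with per-OTU domain
#' labels (bacteria or fungi) and per-sample metadata (compartment and
#' replicate). It is the common currency of the preparation, correlation and
#' network stages.
#'
#' @param values Numeric matrix, OTUs in rows (rownames = OTU ids), samples in
#'   columns (colnames = sample ids). All values must be nonnegative.
#' @param domain Character vector, one of `"bacteria"`/`"fungi"` per OTU.
#' @param samples Data frame with columns `sample_id`, `compartment`
#'   (one of Non, Rhi, Epi, Endo) and `replicate` (integer), one row per
#'   column of `values`.
#' @param mode Either `"counts"` or `"relative"`. In relative mode every
#'   column must sum to 1 (tolerance 1e-9).
#' @return A tibble of class `abund_tbl` with columns `otu_id`, `domain` and
#'   one numeric column per sample; sample metadata is carried in the
#'   `samples` attribute and the value mode in the `mode` attribute.
#' @export
abundance_table <- function(values, domain, samples, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("`values` must have OTU ids as rownames", call. = FALSE)
  if (is.null(colnames(values))) stop("`values` must have sample ids as colnames", call. = FALSE)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "compartment", "replicate") %in% names(samples)))
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop("duplicate OTU id: ", dup, call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(rowSums(values < 0) > 0)[1]
    stop("negative abundance in OTU ", rownames(values)[bad], call. = FALSE)
  }
  if (!all(domain %in% DOMAINS)) stop("domain labels must be 'bacteria' or 'fungi'", call. = FALSE)
  if (length(domain) != nrow(values)) stop("one domain label per OTU required", call. = FALSE)
  missing_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) absent from metadata: ", paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  bad_comp <- setdiff(unique(samples$compartment), COMPARTMENTS)
  if (length(bad_comp)) {
    stop("unknown compartment label(s): ", paste(bad_comp, collapse = ", "), call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample_id), ]
  if (mode == "relative") {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9)) stop("relative-abundance columns must sum to 1", call. = FALSE)
  }
  out <- tibble::tibble(otu_id = rownames(values), domain = domain)
  out <- dplyr::bind_cols(out, tibble::as_tibble(values, .name_repair = "minimal"))
  structure(out,
    samples = samples, mode = mode,
    class = c("abund_tbl", class(out))
  )
}

#' @export
print.abund_tbl <- function(x, ...) {
  meta <- sample_meta(x)
  cat(sprintf(
    "<abund_tbl> %d OTUs (%d bacteria, %d fungi) x %d samples [%s]\n",
    nrow(x), sum(x$domain == "bacteria"), sum(x$domain == "fungi"),
    nrow(meta), attr(x, "mode")
  ))
  NextMethod()
}

#' Sample metadata of an abundance table
#' @param x An `abund_tbl`.
#' @return Tibble with `sample_id`, `compartment`, `replicate`.
#' @export
sample_meta <- function(x) attr(x, "samples")

#' Extract the numeric OTU-by-sample matrix
#' @param x An `abund_tbl`.
#' @return Numeric matrix with OTU ids as rownames.
#' @export
abundance_matrix <- function(x) {
  m <- as.matrix(x[, sample_meta(x)$sample_id, drop = FALSE])
  rownames(m) <- x$otu_id
  m
}

# rebuild an abund_tbl from a row/column subset of the matrix
rebuild_abund <- function(x, keep_otus = NULL, keep_samples = NULL,
                          values = NULL, mode = NULL) {
  m <- values %||% abundance_matrix(x)
  dom <- stats::setNames(x$domain, x$otu_id)
  if (!is.null(keep_otus)) {
    m <- m[keep_otus, , drop = FALSE]
    if ((mode %||% attr(x, "mode")) == "relative") {
      m <- sweep(m, 2, colSums(m), "/") # re-close the composition
    }
  }
  if (!is.null(keep_samples)) m <- m[, keep_samples, drop = FALSE]
  meta <- sample_meta(x)
  meta <- meta[meta$sample_id %in% colnames(m), ]
  abundance_table(m, unname(dom[rownames(m)]), meta, mode = mode %||% attr(x, "mode"))
}

#' Read an abundance table with its sample metadata
#'
#' Reads a tab-separated OTU-by-sample matrix (first column OTU id, one
#' column per sample) together with a metadata table mapping each sample to
#' its compartment and replicate. Malformed input is reported with the
#' offending OTU or sample named.
#'
#' @param path Path to the tab-separated abundance file. Lines starting with
#'   `#` are treated as comments.
#' @param metadata Path to a tab-separated metadata file with columns
#'   `sample_id`, `compartment`, `replicate`, or a data frame with those
#'   columns.
#' @param domain Domain label applied to all OTUs in the file
#'   (`"bacteria"` or `"fungi"`), or the name of a per-row column in the
#'   file holding the label.
#' @return An [abundance_table()] in counts mode.
#' @export
read_abundance <- function(path, metadata, domain = c("bacteria", "fungi")) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (is.character(metadata) && length(metadata) == 1) {
    metadata <- readr::read_tsv(metadata, comment = "#", show_col_types = FALSE, progress = FALSE)
  }
  metadata <- tibble::as_tibble(metadata)
  if (ncol(tab) < 2) stop("abundance file needs an OTU id column plus sample columns", call. = FALSE)
  names(tab)[1] <- "otu_id"
  dom_col <- if (length(domain) == 1 && domain %in% names(tab)) {
    domain
  } else if ("domain" %in% names(tab)) {
    "domain" # per-row labels present in the file itself
  } else {
    NULL
  }
  if (!is.null(dom_col)) {
    dom <- tab[[dom_col]]
    tab[[dom_col]] <- NULL
  } else {
    dom <- rep(match.arg(domain), nrow(tab))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric abundance values in ", path, call. = FALSE)
  bad <- which(rowSums(vals < 0) > 0)
  if (length(bad)) {
    stop(sprintf(
      "negative count for OTU %s (line %d of %s)",
      tab$otu_id[bad[1]], bad[1] + 1L, path
    ), call. = FALSE)
  }
  if (anyDuplicated(tab$otu_id)) {
    stop("duplicate OTU id in ", path, ": ",
      tab$otu_id[duplicated(tab$otu_id)][1],
      call. = FALSE
    )
  }
  rownames(vals) <- tab$otu_id
  abundance_table(vals, dom, metadata, mode = "counts")
}

#' Restrict an abundance table to one compartment
#' @param x An `abund_tbl`.
#' @param compartment One of `"Non"`, `"Rhi"`, `"Epi"`, `"Endo"`.
#' @return An `abund_tbl` containing only that compartment's samples.
#' @export
filter_compartment <- function(x, compartment) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  meta <- sample_meta(x)
  keep <- meta$sample_id[meta$compartment == compartment]
  if (!length(keep)) stop("no samples in compartment ", compartment, call. = FALSE)
  rebuild_abund(x, keep_samples = keep)
}

#' Prevalence (detection) filter
#'
#' Retains the OTUs detected (strictly positive value) in at least
#' `min_detected` of the replicate samples; the replicate-based co-occurrence
#' analysis uses the 8-of-12 rule. The table must already be restricted to a
#' single compartment with exactly `of_replicates` samples. OTU order is
#' preserved and the operation is idempotent.
#'
#' @param x An `abund_tbl` for one compartment.
#' @param min_detected Minimum number of samples with a positive value
#'   (default 8).
#' @param of_replicates Required number of replicate samples (default 12).
#' @return Filtered `abund_tbl`.
#' @export
prevalence_filter <- function(x, min_detected = 8, of_replicates = 12) {
  meta <- sample_meta(x)
  if (length(unique(meta$compartment)) != 1) {
    stop("prevalence_filter expects a single-compartment table", call. = FALSE)
  }
  if (nrow(meta) != of_replicates) {
    stop(sprintf(
      "expected %d replicate samples, found %d",
      of_replicates, nrow(meta)
    ), call. = FALSE)
  }
  m <- abundance_matrix(x)
  keep <- rownames(m)[rowSums(m > 0) >= min_detected]
  rebuild_abund(x, keep_otus = keep)
}

#' Total-abundance pre-filter
#'
#' Drops OTUs contributing no more than `min_fraction` of the total reads in
#' the table (default 0.01%), mirroring the usual abundance cut applied when
#' OTU tables are assembled.
#'
#' @param x An `abund_tbl` in counts mode.
#' @param min_fraction Minimum fraction of total reads (strict; default 1e-4).
#' @return Filtered `abund_tbl`.
#' @export
abundance_cut <- function(x, min_fraction = 1e-4) {
  m <- abundance_matrix(x)
  frac <- rowSums(m) / sum(m)
  rebuild_abund(x, keep_otus = rownames(m)[frac > min_fraction])
}

#' Convert counts to per-sample relative abundances
#'
#' @param x An `abund_tbl` in counts mode.
#' @return An `abund_tbl` in relative mode; every column sums to 1.
#' @export
to_relative_abundance <- function(x) {
  if (attr(x, "mode") != "counts") stop("table already in relative-abundance mode", call. = FALSE)
  m <- abundance_matrix(x)
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("all-zero sample column(s): ",
      paste(colnames(m)[cs == 0], collapse = ", "),
      call. = FALSE
    )
  }
  rebuild_abund(x, values = sweep(m, 2, cs, "/"), mode = "relative")
}

#' Concatenate bacterial and fungal tables for BFA analysis
#'
#' Row-concatenates two single-domain tables observed on the same samples,
#' producing the mixed table from which the bacterial-fungal association
#' (BFA) network is built. OTU id namespaces must not collide (the
#' OTUB_/OTUF_ prefixes keep them distinct).
#'
#' @param bact,fungi `abund_tbl`s in the same mode with identical sample sets
#'   and ordering.
#' @return Combined `abund_tbl`.
#' @export
merge_domains <- function(bact, fungi) {
  ma <- abundance_matrix(bact)
  mb <- abundance_matrix(fungi)
  if (!identical(colnames(ma), colnames(mb))) {
    diff <- union(setdiff(colnames(ma), colnames(mb)), setdiff(colnames(mb), colnames(ma)))
    msg <- if (length(diff)) paste(diff, collapse = ", ") else "sample order differs"
    stop("sample sets differ between domains: ", msg, call. = FALSE)
  }
  if (attr(bact, "mode") != attr(fungi, "mode")) stop("tables are in different modes", call. = FALSE)
  clash <- intersect(bact$otu_id, fungi$otu_id)
  if (length(clash)) stop("OTU id collision across domains: ", clash[1], call. = FALSE)
  m <- rbind(ma, mb)
  if (attr(bact, "mode") == "relative") {
    m <- sweep(m, 2, colSums(m), "/") # renormalise over the merged community
  }
  abundance_table(m, c(bact$domain, fungi$domain), sample_meta(bact),
    mode = attr(bact, "mode")
  )
}

#' Split a mixed table back into single-domain tables
#' @param x An `abund_tbl`.
#' @return Named list with `bacteria` and `fungi` tables (absent domains dropped).
#' @export
split_domains <- function(x) {
  present <- intersect(DOMAINS, unique(x$domain))
  out <- lapply(present, function(d) rebuild_abund(x, keep_otus = x$otu_id[x$domain == d]))
  stats::setNames(out, present)
}

#' Write an abundance table as tab-separated text
#' @param x An `abund_tbl`.
#' @param path Output file for the matrix.
#' @param metadata_path Optional output file for the sample metadata.
#' @param comment Optional character vector written as `#`-prefixed header
#'   lines (e.g. generator parameters and seed); [read_abundance()] skips
#'   them.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path, metadata_path = NULL, comment = NULL) {
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE, append = TRUE, col_names = TRUE)
    if (!is.null(metadata_path)) readr::write_tsv(sample_meta(x), metadata_path, progress = FALSE)
    return(invisible(path))
  }
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  if (!is.null(metadata_path)) readr::write_tsv(sample_meta(x), metadata_path, progress = FALSE)
  invisible(path)
}

#' Tidy an abundance table into long format
#' @param x An `abund_tbl`.
#' @param ... Unused.
#' @return Long tibble: `otu_id`, `domain`, `sample_id`, `compartment`,
#'   `replicate`, `abundance`.
#' @method tidy abund_tbl
#' @export
tidy.abund_tbl <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(x), -c("otu_id", "domain"),
    names_to = "sample_id", values_to = "abundance"
  )
  dplyr::left_join(long, sample_meta(x), by = "sample_id")
}
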