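#' Assemble a metabolomics cohort object
#'
#' A `metab_cohort` bundles a samples-by-metabolites intensity matrix with its
#' sample and metabolite metadata. Missing measurements are `NA` in the matrix;
#' a measured zero stays zero (presence filtering distinguishes the two).
#'
#' @param values numeric matrix, samples in rows, metabolites in columns.
#'   Finite values must be non-negative; `NA` marks a missing measurement.
#' @param samples tibble of sample metadata with columns `sample_id`,
#'   `subject_id`, `pair_id`, `group` (one of DEL, CNT, QC, BLANK,
#'   CONDITIONING), `timepoint` (PREOP, POD2 or NA), `run_id`,
#'   `injection_order`. One row per matrix row, in order.
#' @param metabolites tibble of metabolite metadata with columns
#'   `metabolite_id`, `display_name`, `is_internal_standard`, `library_ids`.
#'   One row per matrix column, in order.
#'
#' @return an object of class `metab_cohort`.
#' @export
metab_cohort <- function(values, samples, metabolites = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- tibble::as_tibble(samples)
  if (is.null(metabolites)) {
    metabolites <- default_metabolite_meta(colnames(values))
  }
  metabolites <- tibble::as_tibble(metabolites)
  if (!"display_name" %in% names(metabolites)) {
    metabolites$display_name <- metabolites$metabolite_id
  }
  if (!"is_internal_standard" %in% names(metabolites)) {
    metabolites$is_internal_standard <- FALSE
  }
  rownames(values) <- samples$sample_id
  colnames(values) <- metabolites$metabolite_id
  x <- structure(
    list(values = values, samples = samples, metabolites = metabolites),
    class = "metab_cohort"
  )
  validate_cohort(x)
  x
}

default_metabolite_meta <- function(ids) {
  tibble::tibble(
    metabolite_id = ids,
    display_name = ids,
    is_internal_standard = FALSE
  )
}

# STANDARD covers designs that inject spike-in standards as their own
# samples; such rows are parsed and carried but take no part in the analysis
# (the normalization reads standards as flagged metabolite channels).
GROUP_LEVELS <- c("DEL", "CNT", "QC", "BLANK", "CONDITIONING", "STANDARD")
TIMEPOINT_LEVELS <- c("PREOP", "POD2")

validate_cohort <- function(x) {
  stopifnot(inherits(x, "metab_cohort"))
  v <- x$values
  s <- x$samples
  m <- x$metabolites
  if (nrow(v) != nrow(s)) stop("sample metadata rows must match matrix rows", call. = FALSE)
  if (ncol(v) != nrow(m)) stop("metabolite metadata rows must match matrix columns", call. = FALSE)
  req <- c("sample_id", "group", "run_id", "injection_order")
  miss <- setdiff(req, names(s))
  if (length(miss)) stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(s$sample_id)) stop("duplicate sample_id", call. = FALSE)
  if (anyDuplicated(m$metabolite_id)) stop("duplicate metabolite_id", call. = FALSE)
  bad <- setdiff(unique(as.character(s$group)), GROUP_LEVELS)
  if (length(bad)) stop("unknown group token(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(v[is.finite(v)] < 0)) stop("negative intensity values are not allowed", call. = FALSE)
  dup_ord <- s |>
    dplyr::count(.data$run_id, .data$injection_order) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup_ord)) stop("injection_order must be unique within run_id", call. = FALSE)
  study <- s$group %in% c("DEL", "CNT")
  if (any(study)) {
    ss <- s[study, ]
    if (!all(c("pair_id", "timepoint") %in% names(s)) ||
        anyNA(ss$pair_id) || anyNA(ss$timepoint)) {
      stop("DEL/CNT samples require non-missing pair_id and timepoint", call. = FALSE)
    }
    chk <- ss |>
      dplyr::count(.data$pair_id, .data$timepoint, .data$group) |>
      dplyr::filter(.data$n != 1L)
    if (nrow(chk)) {
      stop("each pair_id must map to exactly one DEL and one CNT sample per timepoint", call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.metab_cohort <- function(x, ...) {
  tab <- table(factor(x$samples$group, GROUP_LEVELS))
  cat("<metab_cohort> ", nrow(x$values), " samples x ", ncol(x$values),
      " metabolites\n", sep = "")
  cat("  samples: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  cat("  internal standards: ", sum(x$metabolites$is_internal_standard),
      "; missing cells: ", sum(is.na(x$values)),
      sprintf(" (%.2f%%)", 100 * mean(is.na(x$values))), "\n", sep = "")
  invisible(x)
}

#' @export
dim.metab_cohort <- function(x) dim(x$values)

#' Extract cohort pieces as tibbles
#'
#' `cohort_samples()` and `cohort_metabolites()` return the metadata tables;
#' `cohort_values()` the numeric matrix; `cohort_long()` a long tibble
#' (one row per sample-metabolite cell) convenient for dplyr/ggplot2 work.
#'
#' @param x a `metab_cohort`.
#' @return a tibble (or matrix for `cohort_values()`).
#' @export
cohort_samples <- function(x) x$samples

#' @rdname cohort_samples
#' @export
cohort_metabolites <- function(x) x$metabolites

#' @rdname cohort_samples
#' @export
cohort_values <- function(x) x$values

#' @rdname cohort_samples
#' @export
cohort_long <- function(x) {
  tibble::as_tibble(x$values) |>
    dplyr::mutate(sample_id = x$samples$sample_id, .before = 1L) |>
    tidyr::pivot_longer(-"sample_id",
                        names_to = "metabolite_id", values_to = "value") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

#' Subset a cohort by samples and/or metabolites
#'
#' @param x a `metab_cohort`.
#' @param samples logical/integer/character index over samples (rows).
#' @param metabolites logical/integer/character index over metabolites.
#' @return a `metab_cohort`.
#' @export
cohort_subset <- function(x, samples = NULL, metabolites = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(x$values)) else samples
  if (is.character(si)) si <- match(si, x$samples$sample_id)
  mi <- if (is.null(metabolites)) seq_len(ncol(x$values)) else metabolites
  if (is.character(mi)) mi <- match(mi, x$metabolites$metabolite_id)
  metab_cohort(x$values[si, mi, drop = FALSE],
               x$samples[si, , drop = FALSE],
               x$metabolites[mi, , drop = FALSE])
}

#' Canonical acquisition order
#'
#' Reorders samples by (run_id, injection_order), the order in which the
#' instrument acquired them; drift correction assumes this ordering.
#'
#' @param x a `metab_cohort`.
#' @return a `metab_cohort` with rows sorted by acquisition.
#' @export
cohort_canonical_order <- function(x) {
  ord <- order(x$samples$run_id, x$samples$injection_order)
  cohort_subset(x, samples = ord)
}

#' Global injection index across runs
#'
#' Samples ordered by (run_id, injection_order) receive consecutive global
#' indices; used as the drift-regression abscissa when runs are bridged
#' through the shared pooled-QC series.
#'
#' @param x a `metab_cohort`.
#' @return integer vector aligned with the cohort's sample rows.
#' @export
global_injection_index <- function(x) {
  ord <- order(x$samples$run_id, x$samples$injection_order)
  idx <- integer(nrow(x$samples))
  idx[ord] <- seq_along(ord)
  idx
}

is_study_sample <- function(x) x$samples$group %in% c("DEL", "CNT")
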