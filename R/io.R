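#' Read an intensity matrix from disk
#'
#' Two dialects are supported. `wide`: one row per sample, the sample-metadata
#' columns (`sample_id`, optionally `subject_id`, `pair_id`, `group`,
#' `timepoint`, `run_id`, `injection_order`) first, followed by one numeric
#' column per metabolite. `long`: columns `sample_id`, `metabolite_id`,
#' `value`, optionally accompanied by the same sample-metadata columns
#' repeated on each row. Empty cells and `NA` tokens become the missing
#' state; measured zeros are kept as zeros.
#'
#' @param path path to a CSV (comma) or TSV (tab) file; the delimiter is
#'   sniffed from the header line.
#' @param dialect `"wide"` or `"long"`.
#' @param metabolite_meta optional path to a TSV with columns
#'   `metabolite_id`, `display_name`, `is_internal_standard` (and optionally
#'   `library_ids`, semicolon-separated) used to flag internal standards.
#' @return a [metab_cohort()].
#' @export
read_intensity_matrix <- function(path, dialect = c("wide", "long"),
                                  metabolite_meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                          show_col_types = FALSE, progress = FALSE)
  meta_cols <- c("sample_id", "subject_id", "pair_id", "group", "timepoint",
                 "run_id", "injection_order")
  if (dialect == "wide") {
    if (!"sample_id" %in% names(df)) stop("wide matrix needs a sample_id column", call. = FALSE)
    present_meta <- intersect(meta_cols, names(df))
    samples <- complete_sample_meta(df[present_meta])
    value_cols <- setdiff(names(df), meta_cols)
    values <- vapply(df[value_cols], as_numeric_checked, numeric(nrow(df)))
    if (is.null(dim(values))) values <- matrix(values, nrow = nrow(df),
                                               dimnames = list(NULL, value_cols))
  } else {
    need <- c("sample_id", "metabolite_id", "value")
    if (!all(need %in% names(df))) {
      stop("long matrix needs columns sample_id, metabolite_id, value", call. = FALSE)
    }
    if (anyDuplicated(df[c("sample_id", "metabolite_id")])) {
      stop("duplicate sample_id/metabolite_id entries in long file", call. = FALSE)
    }
    samples <- df |>
      dplyr::select(dplyr::any_of(meta_cols)) |>
      dplyr::distinct(.data$sample_id, .keep_all = TRUE) |>
      complete_sample_meta()
    wide <- df |>
      dplyr::select("sample_id", "metabolite_id", "value") |>
      tidyr::pivot_wider(names_from = "metabolite_id", values_from = "value")
    wide <- wide[match(samples$sample_id, wide$sample_id), ]
    values <- vapply(wide[-1L], as_numeric_checked, numeric(nrow(wide)))
    if (is.null(dim(values))) values <- matrix(values, nrow = nrow(wide),
                                               dimnames = list(NULL, names(wide)[-1L]))
  }
  metab <- default_metabolite_meta(colnames(values))
  if (!is.null(metabolite_meta)) {
    mm <- readr::read_tsv(metabolite_meta, show_col_types = FALSE, progress = FALSE)
    metab <- metab |>
      dplyr::select("metabolite_id") |>
      dplyr::left_join(mm, by = "metabolite_id")
    if (!"display_name" %in% names(metab) || anyNA(metab$display_name)) {
      metab$display_name <- dplyr::coalesce(metab$display_name, metab$metabolite_id)
    }
    metab$is_internal_standard <- isTRUE_vec(metab$is_internal_standard)
  }
  metab_cohort(values, samples, metab)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# coerce a parsed column to double, erroring on genuinely non-numeric tokens
as_numeric_checked <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.logical(x) && all(is.na(x))) return(as.numeric(x))
  y <- suppressWarnings(as.numeric(x))
  if (any(!is.na(x) & is.na(y))) stop("non-numeric intensity values", call. = FALSE)
  y
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

complete_sample_meta <- function(s) {
  s <- tibble::as_tibble(s)
  n <- nrow(s)
  if (!"subject_id" %in% names(s)) s$subject_id <- NA_character_
  if (!"pair_id" %in% names(s)) s$pair_id <- NA_character_
  if (!"group" %in% names(s)) s$group <- "QC"
  if (!"timepoint" %in% names(s)) s$timepoint <- NA_character_
  if (!"run_id" %in% names(s)) s$run_id <- 1L
  if (!"injection_order" %in% names(s)) s$injection_order <- seq_len(n)
  s$group <- toupper(as.character(s$group))
  s$run_id <- as.integer(s$run_id)
  s$injection_order <- as.integer(s$injection_order)
  s[c("sample_id", "subject_id", "pair_id", "group", "timepoint",
      "run_id", "injection_order")]
}

#' Write an intensity matrix to disk
#'
#' Inverse of [read_intensity_matrix()]; missing cells are written as empty
#' strings (wide CSV) or `NA` (long TSV), zeros are written as zeros. Numeric
#' output uses up to 15 significant digits so write-then-read round-trips to
#' better than 12 significant digits.
#'
#' @param x a [metab_cohort()].
#' @param path output file path (`.csv` for wide, `.tsv` for long).
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  v <- x$values
  fmt <- function(z) ifelse(is.na(z), NA_character_,
                            formatC(z, digits = 15, format = "g"))
  if (dialect == "wide") {
    df <- dplyr::bind_cols(
      x$samples,
      tibble::as_tibble(matrix(fmt(v), nrow = nrow(v),
                               dimnames = dimnames(v)))
    )
    readr::write_csv(df, path, na = "", progress = FALSE)
  } else {
    long <- cohort_long(x) |>
      dplyr::mutate(value = fmt(.data$value)) |>
      dplyr::select("sample_id", "metabolite_id", "value", "subject_id",
                    "pair_id", "group", "timepoint", "run_id",
                    "injection_order")
    readr::write_tsv(long, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Write metabolite metadata alongside a matrix
#'
#' @param x a [metab_cohort()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_metabolite_meta <- function(x, path) {
  m <- x$metabolites
  if ("library_ids" %in% names(m) && is.list(m$library_ids)) {
    m$library_ids <- vapply(m$library_ids, paste, "", collapse = ";")
  }
  readr::write_tsv(m, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a pathway library (GMT sets plus optional graph edges)
#'
#' GMT lines are `name<TAB>description<TAB>compound ids...`; compounds
#' duplicated within a line are counted once. The universe defaults to the
#' union of all set members and can be overridden downstream. The optional
#' edge file has columns `pathway_id`, `node_a`, `node_b` and supplies an
#' undirected graph per pathway for topology impact; an edge naming a
#' compound outside its pathway's set is an error.
#'
#' @param sets_path GMT file path.
#' @param edges_path optional TSV edge list path.
#' @return a `pathway_library`: list with `pathways` (tibble: pathway_id,
#'   name, size), `sets` (named list of character vectors), `graphs`
#'   (named list of igraph objects or `NULL`), `universe`.
#' @export
read_pathway_library <- function(sets_path, edges_path = NULL) {
  lines <- readLines(sets_path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1], call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate pathway id in GMT", call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- ids
  graphs <- stats::setNames(vector("list", length(ids)), ids)
  if (!is.null(edges_path)) {
    ed <- readr::read_tsv(edges_path, show_col_types = FALSE, progress = FALSE)
    need <- c("pathway_id", "node_a", "node_b")
    if (!all(need %in% names(ed))) stop("edge file needs pathway_id, node_a, node_b", call. = FALSE)
    for (pid in unique(ed$pathway_id)) {
      if (!pid %in% ids) stop("edge references unknown pathway: ", pid, call. = FALSE)
      sub <- ed[ed$pathway_id == pid, ]
      nodes <- union(sub$node_a, sub$node_b)
      outside <- setdiff(nodes, sets[[pid]])
      if (length(outside)) {
        stop("edge in ", pid, " references compound outside its set: ",
             outside[1], call. = FALSE)
      }
      g <- igraph::graph_from_data_frame(sub[c("node_a", "node_b")],
                                         directed = FALSE,
                                         vertices = sets[[pid]])
      graphs[[pid]] <- igraph::simplify(g)
    }
  }
  structure(
    list(
      pathways = tibble::tibble(
        pathway_id = ids,
        name = vapply(parts, `[[`, "", 2L),
        size = unname(lengths(sets))
      ),
      sets = sets,
      graphs = graphs,
      universe = sort(unique(unlist(sets)))
    ),
    class = "pathway_library"
  )
}

#' @export
print.pathway_library <- function(x, ...) {
  cat("<pathway_library> ", nrow(x$pathways), " pathways, universe ",
      length(x$universe), " compounds, ",
      sum(!vapply(x$graphs, is.null, TRUE)), " with graphs\n", sep = "")
  invisible(x)
}

#' Write result tables with a deterministic layout
#'
#' Univariate tables are written with columns (metabolite, VIP, AVG_p, FC, ...)
#' sorted by ascending AVG_p with ties broken by metabolite id; enrichment
#' tables with columns (pathway, Total, Expected, Hits, Raw.p, FDR, Impact)
#' sorted by raw p. Numbers use fixed formatting so identical inputs yield
#' byte-identical files.
#'
#' @param results a tibble from [univariate_table()] or [enrich_pathways()],
#'   or an `opls_model`.
#' @param out_dir output directory (created if needed).
#' @return character vector of paths written, invisibly.
#' @export
write_report_tables <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L) {
    stop("cannot write to directory: ", out_dir, call. = FALSE)
  }
  fmt_num <- function(z) ifelse(is.na(z), "NA", formatC(z, digits = 6, format = "g"))
  paths <- character(0)
  if (inherits(results, "opls_model")) {
    path <- file.path(out_dir, "opls_summary.tsv")
    readr::write_tsv(dplyr::mutate(glance(results),
                                   dplyr::across(dplyr::where(is.numeric), fmt_num)),
                     path, progress = FALSE)
    return(invisible(path))
  }
  df <- tibble::as_tibble(results)
  if ("metabolite_id" %in% names(df)) {
    keep <- intersect(c("metabolite_id", "VIP", "AVG_p", "FC", "b_log2",
                        "p_t", "p_wilcoxon", "p_binomial",
                        "q_t", "q_wilcoxon", "q_binomial",
                        "n_tests_passed", "consensus",
                        "robust_fraction", "robust"), names(df))
    df <- df[keep]
    sort_key <- if ("AVG_p" %in% names(df)) df$AVG_p else rep(NA_real_, nrow(df))
    df <- df[order(!is.finite(sort_key), sort_key, df$metabolite_id), ]
    path <- file.path(out_dir, "univariate_table.tsv")
  } else if ("pathway_id" %in% names(df)) {
    keep <- intersect(c("pathway_id", "name", "Total", "Expected", "Hits",
                        "raw_p", "FDR", "Impact"), names(df))
    df <- df[keep]
    df <- df[order(df$raw_p, df$pathway_id), ]
    path <- file.path(out_dir, "enrichment_table.tsv")
  } else {
    stop("unrecognized results table", call. = FALSE)
  }
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), fmt_num))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
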