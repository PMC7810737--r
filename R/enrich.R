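#' Map metabolite names onto a pathway library
#'
#' Case-insensitive exact matching on compound id or display name after
#' punctuation/whitespace normalization; duplicates count once and names
#' that fail to map are reported rather than silently dropped.
#'
#' @param names character vector of metabolite names or ids.
#' @param library a `pathway_library` from [read_pathway_library()].
#' @return list: `mapped` (compound ids found in the library universe),
#'   `unmapped` (input names with no match).
#' @export
map_input <- function(names, library) {
  norm <- function(z) gsub("[[:punct:][:space:]]+", "", tolower(z))
  uni <- library$universe
  key <- norm(uni)
  inp <- unique(names)
  idx <- match(norm(inp), key)
  list(mapped = uni[idx[!is.na(idx)]], unmapped = inp[is.na(idx)])
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway of size K in a universe of N compounds, with n mapped
#' input compounds and `Hits` of them inside the pathway, the raw p-value is
#' the exact upper tail P(X >= Hits), X ~ Hypergeometric(N, K, n), and
#' `Expected` = K * n / N. FDR is Benjamini-Hochberg across the library
#' (see [fdr_over_pathways()]); topology `Impact` is the summed normalized
#' betweenness of the hit compounds when a pathway graph is available.
#'
#' @param mapped character vector of mapped compound ids (use [map_input()]).
#' @param library a `pathway_library`.
#' @param universe optional universe override (e.g. the assay panel);
#'   defaults to the library universe.
#' @return tibble sorted by raw p: `pathway_id`, `name`, `Total`,
#'   `Expected`, `Hits`, `raw_p`, `FDR`, `Impact`.
#' @export
ora_hypergeometric <- function(mapped, library, universe = NULL) {
  uni <- unique(universe %||% library$universe)
  mapped <- intersect(unique(mapped), uni)
  n <- length(mapped)
  N <- length(uni)
  if (n < 1L) stop("no mapped input compounds", call. = FALSE)
  if (n > N) stop("input larger than universe: library inconsistency", call. = FALSE)
  rows <- purrr::imap(library$sets, function(set, pid) {
    set <- intersect(set, uni)
    K <- length(set)
    hits <- intersect(mapped, set)
    h <- length(hits)
    raw_p <- if (K < 1L) NA_real_
             else stats::phyper(h - 1L, K, N - K, n, lower.tail = FALSE)
    g <- library$graphs[[pid]]
    tibble::tibble(pathway_id = pid, Total = K,
                   Expected = K * n / N, Hits = h, raw_p = raw_p,
                   Impact = if (is.null(g)) NA_real_ else topology_impact(g, hits))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::left_join(library$pathways[c("pathway_id", "name")], by = "pathway_id") |>
    dplyr::relocate("name", .after = "pathway_id")
  out <- fdr_over_pathways(out, m = nrow(library$pathways))
  out[order(out$raw_p, out$pathway_id), ]
}

#' Benjamini-Hochberg FDR across a pathway library
#'
#' Adjusts the raw hypergeometric p-values step-up over `m` pathways. When
#' `m` exceeds the number of rows (a larger library was tested than is
#' reported), the untested pathways are assumed to rank after the reported
#' ones with p = 1, which reduces to multiplying by `m` before the step-up
#' cummin.
#'
#' @param results tibble with a `raw_p` column.
#' @param m family size (defaults to the number of rows).
#' @return the tibble with an `FDR` column.
#' @export
fdr_over_pathways <- function(results, m = nrow(results)) {
  p <- results$raw_p
  if (m < sum(!is.na(p))) stop("m smaller than the number of tested pathways", call. = FALSE)
  ord <- order(p)
  ranked <- p[ord]
  k <- which(!is.na(ranked))
  q <- rep(NA_real_, length(p))
  if (length(k)) {
    adj <- ranked[k] * m / seq_along(k)
    q[ord[k]] <- pmin(1, rev(cummin(rev(adj))))
  }
  results$FDR <- q
  results
}

#' Topology impact of hit compounds in a pathway graph
#'
#' Exact shortest-path betweenness centrality (Brandes) is computed for
#' every node, normalized to sum to one within the pathway, and the impact
#' is the summed weight of the hit nodes. When every node has zero
#' betweenness (e.g. a single edge), weights fall back to uniform.
#'
#' @param graph an undirected igraph over the pathway's compounds.
#' @param hits character vector of hit compound ids.
#' @return impact in `[0, 1]`.
#' @export
topology_impact <- function(graph, hits) {
  bt <- igraph::betweenness(graph, directed = FALSE)
  w <- if (sum(bt) > 0) bt / sum(bt) else rep(1 / length(bt), length(bt))
  names(w) <- igraph::V(graph)$name
  sum(w[intersect(hits, names(w))])
}

#' Enrichment of a significant-metabolite list
#'
#' Convenience wrapper: maps display names, runs the hypergeometric ORA with
#' topology impact, and carries the unmapped names as an attribute.
#'
#' @param sig_names significant metabolite names (e.g. consensus calls).
#' @param library a `pathway_library`.
#' @param universe `"library"` (default: all library compounds) or a
#'   character vector such as the assay panel's compound ids.
#' @return the [ora_hypergeometric()] tibble with attribute `unmapped`.
#' @export
enrich_pathways <- function(sig_names, library, universe = "library") {
  mp <- map_input(sig_names, library)
  uni <- if (identical(universe, "library")) NULL else universe
  out <- ora_hypergeometric(mp$mapped, library, universe = uni)
  attr(out, "unmapped") <- mp$unmapped
  out
}
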