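# Degree statistics of protein-protein interaction graphs.

#' Degree summary of an interaction graph
#'
#' Computes per-node degrees (isolated nodes count, with degree 0), the
#' node-fraction degree distribution `P(k)`, the per-protein connection
#' probability `degree / 2E` (each protein's share of all edge
#' endpoints — distinct from `P(k)`, though the two are easily conflated),
#' and the average node degree `<d> = 2E / N`.
#'
#' @param graph a [ppi_graph()].
#' @return object of class `degree_summary`: `degree_of` (named by
#'   protein id), `distribution` (named by degree), `connection_prob`,
#'   `mean_degree`, `n_nodes`, `n_edges`.
#' @examples
#' g <- ppi_graph(c("A", "B", "C"),
#'                rbind(c("A", "B"), c("B", "C"), c("A", "C")))
#' summarize_degrees(g)$mean_degree  # 2
#' @export
summarize_degrees <- function(graph) {
  stopifnot(inherits(graph, "ppi_graph"))
  n <- length(graph$nodes)
  if (n == 0) stop_empty_input("graph has no nodes")
  e <- nrow(graph$edges)
  deg <- stats::setNames(rep(0L, n), graph$nodes)
  if (e > 0) {
    tab <- table(c(graph$edges[, 1], graph$edges[, 2]))
    deg[names(tab)] <- as.integer(tab)
  }
  dist_tab <- table(deg) / n
  distribution <- stats::setNames(as.vector(dist_tab), names(dist_tab))
  conn <- if (e > 0) deg / (2 * e) else deg * NA_real_
  structure(
    list(degree_of = deg,
         distribution = distribution,
         connection_prob = conn,
         mean_degree = 2 * e / n,
         n_nodes = n,
         n_edges = e),
    class = "degree_summary"
  )
}

#' @export
print.degree_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Degree summary: N = %d nodes, E = %d edges, <d> = 2E/N = %s\n",
              x$n_nodes, x$n_edges, format(x$mean_degree, digits = digits)))
  invisible(x)
}

#' Average degree by homo-oligomer class
#'
#' Joins graph nodes to protein records on `protein_id` and reports, for
#' each requested subunit class k, the number of member proteins found in
#' the graph and their arithmetic mean degree. Proteins annotated with a
#' class but absent from the graph are excluded from the mean (interaction
#' databases only list interacting proteins) and counted in
#' `n_not_in_graph`. The share of annotated proteins found in the graph is
#' reported in the `join_rate` attribute.
#'
#' @param graph a [ppi_graph()].
#' @param records protein-record data frame with `protein_id` and
#'   `oligomer_k`.
#' @param classes subunit classes to summarize (default the even classes
#'   2, 4, 6, 8).
#' @return data frame of class `class_degree_table` with columns `k`,
#'   `n_members`, `n_not_in_graph`, `mean_degree`; attribute `join_rate`.
#' @export
degree_by_oligomer_class <- function(graph, records, classes = c(2, 4, 6, 8)) {
  stopifnot(inherits(graph, "ppi_graph"))
  ds <- summarize_degrees(graph)
  known <- records[!is.na(records$oligomer_k), , drop = FALSE]
  in_graph <- known$protein_id %in% names(ds$degree_of)
  if (!any(in_graph)) {
    stop_empty_input("no annotated protein is present in the graph")
  }
  rows <- lapply(classes, function(k) {
    members <- known$protein_id[known$oligomer_k == k]
    present <- members[members %in% names(ds$degree_of)]
    data.frame(
      k = k,
      n_members = length(present),
      n_not_in_graph = length(members) - length(present),
      mean_degree = if (length(present) > 0)
        mean(ds$degree_of[present]) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_members > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "join_rate") <- mean(in_graph)
  class(out) <- c("class_degree_table", "data.frame")
  out
}

#' Correlation between mean degree and subunit number
#'
#' Pearson correlation and OLS slope of mean class degree `<d>_k` against
#' subunit number k, quantifying whether connectivity varies with
#' oligomerization state (in real interaction data it is homogeneous
#' across classes). A table with constant `<d>_k` has zero covariance, so
#' the correlation is defined as 0 (and the slope is 0) rather than NaN.
#'
#' @param table a [degree_by_oligomer_class()] result (or any data frame
#'   with `k` and `mean_degree`).
#' @return list with `r` (Pearson), `slope`, and `n_classes`.
#' @export
correlation_degree_vs_k <- function(table) {
  tab <- table[!is.na(table$mean_degree), , drop = FALSE]
  if (nrow(tab) < 3) {
    stop_insufficient_data("need at least 3 classes with a mean degree")
  }
  if (stats::sd(tab$mean_degree) == 0) {
    return(list(r = 0, slope = 0, n_classes = nrow(tab)))
  }
  r <- stats::cor(tab$k, tab$mean_degree)
  slope <- unname(stats::coef(stats::lm(mean_degree ~ k, data = tab))[2])
  list(r = r, slope = slope, n_classes = nrow(tab))
}

#' Serialize a degree summary to JSON and tidy TSV
#'
#' Writes `<stem>.json` with the scalar fields and degree distribution,
#' and `<stem>.tsv` with one row per protein (`protein_id`, `degree`,
#' `oligomer_k` if records are supplied).
#'
#' @param summary a `degree_summary`.
#' @param path_stem output path without extension.
#' @param records optional protein records used to attach `oligomer_k`.
#' @return files written, invisibly.
#' @export
write_degree_summary <- function(summary, path_stem, records = NULL) {
  stopifnot(inherits(summary, "degree_summary"))
  jf <- paste0(path_stem, ".json")
  jsonlite::write_json(
    list(n_nodes = summary$n_nodes, n_edges = summary$n_edges,
         mean_degree = summary$mean_degree,
         distribution = as.list(summary$distribution)),
    jf, auto_unbox = TRUE, digits = NA)
  df <- data.frame(protein_id = names(summary$degree_of),
                   degree = unname(summary$degree_of),
                   stringsAsFactors = FALSE)
  if (!is.null(records)) {
    df$oligomer_k <- records$oligomer_k[match(df$protein_id,
                                              records$protein_id)]
  }
  tf <- paste0(path_stem, ".tsv")
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jf, tf))
}
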