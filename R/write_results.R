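#' Write per-subject result graphs and a cohort summary
#'
#' For every subject: an edge-list CSV (`source, target, lag, estimate, se,
#' z, level`) and a GraphML file of the directed network (edge attributes
#' lag, estimate, level). Also writes `cohort_summary.csv` with per-subject
#' path counts and fit indices.
#'
#' @param result a `gimme_result`.
#' @param dir output directory (created if missing).
#' @param atlas a [network_atlas()] used to label nodes.
#' @return Invisibly, the vector of written file paths.
#' @export
write_result_graphs <- function(result, dir, atlas) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  written <- character(0)
  for (id in names(result$edges)) {
    e <- result$edges[[id]]
    out <- data.frame(source = atlas$roi_names[e$source],
                      target = atlas$roi_names[e$target],
                      lag = e$lag, estimate = e$estimate, se = e$se,
                      z = e$z, level = e$level)
    csv <- file.path(dir, paste0(id, "_edges.csv"))
    utils::write.csv(out, csv, row.names = FALSE)
    g <- igraph::graph_from_data_frame(
      out[c("source", "target", "lag", "estimate", "level")],
      directed = TRUE,
      vertices = data.frame(name = atlas$roi_names,
                            network = unname(atlas$network_of)))
    gml <- file.path(dir, paste0(id, ".graphml"))
    igraph::write_graph(g, gml, format = "graphml")
    written <- c(written, csv, gml)
  }
  summ <- data.frame(
    subject_id = names(result$edges),
    n_paths = vapply(result$edges, nrow, integer(1)),
    n_group = vapply(result$edges, function(e) sum(e$level == "group"),
                     integer(1)),
    n_subgroup = vapply(result$edges, function(e) sum(e$level == "subgroup"),
                        integer(1)),
    n_individual = vapply(result$edges,
                          function(e) sum(e$level == "individual"),
                          integer(1)),
    subgroup = result$subgroups$assignment[names(result$edges)],
    CFI = vapply(result$indices, function(i) i$CFI, numeric(1)),
    NNFI = vapply(result$indices, function(i) i$NNFI, numeric(1)),
    RMSEA = vapply(result$indices, function(i) i$RMSEA, numeric(1)),
    SRMR = vapply(result$indices, function(i) i$SRMR, numeric(1)),
    row.names = NULL)
  sp <- file.path(dir, "cohort_summary.csv")
  utils::write.csv(summ, sp, row.names = FALSE)
  invisible(c(written, sp))
}

#' Read a subject edge list written by [write_result_graphs()]
#'
#' @param path path to a `*_edges.csv` file.
#' @return data.frame with the edge-list columns.
#' @export
read_edge_list <- function(path) {
  read_delimited(path)
}
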