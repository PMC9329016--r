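#' Assemble a comorbidity network for one stratum
#'
#' Nodes are the retained diseases (isolated nodes included), annotated with
#' bootstrap mean prevalence and connectivity; edges are the pairs passing
#' the percentile rule with mean phi > 0; density is the mean phi over all
#' candidate pairs.
#'
#' @param result A [bootstrap_pairs()] result.
#' @param edges Significant edge table (default [significant_edges()]).
#' @param prevalence Named prevalence vector (default: bootstrap means from
#'   `result`).
#' @param label Stratum label (default `result$label`).
#' @return An object of class `comorbidity_network`: list with `nodes`
#'   (data.frame disease/prevalence/connectivity), `edges` (data.frame
#'   disease_i/disease_j/mean_phi/phi_p025), `density`, `label`,
#'   `provenance`.
#' @export
build_network <- function(result, edges = significant_edges(result),
                          prevalence = result$prevalence,
                          label = result$label) {
  stopifnot(inherits(result, "bootstrap_result"))
  unknown <- setdiff(unique(c(edges$disease_i, edges$disease_j)),
                     result$diseases)
  if (length(unknown))
    stop("edge references unknown node(s): ", paste(unknown, collapse = ", "))
  edges <- edges[!is.na(edges$mean_phi) & edges$mean_phi > 0 &
                   edges$phi_p025 > 0, , drop = FALSE]
  nodes <- data.frame(
    disease = result$diseases,
    prevalence = unname(prevalence[result$diseases]),
    connectivity = unname(node_connectivity(result)[result$diseases]),
    stringsAsFactors = FALSE)
  structure(list(
    nodes = nodes,
    edges = edges[, c("disease_i", "disease_j", "mean_phi", "phi_p025")],
    density = network_density(result),
    label = label,
    provenance = list(seed = result$config$seed,
                      n_resamples = result$config$n_resamples,
                      resample_size = result$config$resample_size %||%
                        result$n_subjects,
                      percentile = result$config$percentile,
                      n_subjects = result$n_subjects)),
    class = "comorbidity_network")
}

#' @export
print.comorbidity_network <- function(x, ...) {
  cat(sprintf("Comorbidity network '%s': %d nodes, %d/%d significant edges, density %.4f\n",
              x$label, nrow(x$nodes), nrow(x$edges),
              nrow(x$nodes) * (nrow(x$nodes) - 1) / 2, x$density))
  invisible(x)
}

#' Rendering attributes for a comorbidity network
#'
#' Node size is proportional to disease prevalence; edge width is
#' proportional to the square of the phi coefficient, so stronger
#' associations stand out quadratically.
#'
#' @param net A [build_network()] result.
#' @param size_scale,width_scale Positive multipliers.
#' @return List with `nodes` (plus `size`) and `edges` (plus `width`).
#' @export
visual_attributes <- function(net, size_scale = 30, width_scale = 40) {
  stopifnot(inherits(net, "comorbidity_network"))
  if (size_scale <= 0 || width_scale <= 0)
    stop("size_scale and width_scale must be positive")
  nodes <- net$nodes
  nodes$size <- size_scale * nodes$prevalence
  edges <- net$edges
  edges$width <- width_scale * edges$mean_phi^2
  list(nodes = nodes, edges = edges)
}

as_igraph <- function(net, size_scale = 30, width_scale = 40) {
  va <- visual_attributes(net, size_scale, width_scale)
  g <- igraph::graph_from_data_frame(
    va$edges, directed = FALSE,
    vertices = data.frame(name = va$nodes$disease,
                          prevalence = va$nodes$prevalence,
                          connectivity = va$nodes$connectivity,
                          size = va$nodes$size))
  g
}

#' Export a comorbidity network
#'
#' GraphML (via igraph; node prevalence/connectivity and edge
#' mean_phi/width travel as attributes), long-format edge-list CSV (one row
#' per significant edge), or JSON matching the schema shipped in
#' `inst/schema/network-schema.json`.
#'
#' @param net A [build_network()] result.
#' @param path Output file path.
#' @param format `"graphml"`, `"edgelist"` or `"json"`.
#' @param ... Passed to [visual_attributes()] for GraphML.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist", "json"),
                           ...) {
  stopifnot(inherits(net, "comorbidity_network"))
  format <- match.arg(format)
  switch(format,
    graphml = igraph::write_graph(as_igraph(net, ...), path,
                                  format = "graphml"),
    edgelist = utils::write.csv(net$edges, path, row.names = FALSE),
    json = writeLines(jsonlite::toJSON(unclass(net), dataframe = "rows",
                                       auto_unbox = TRUE, digits = NA,
                                       pretty = TRUE), path))
  invisible(path)
}

#' Read back a GraphML export
#'
#' @param path A GraphML file written by [export_network()].
#' @return An igraph graph with the exported attributes.
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Plot a comorbidity network
#'
#' Force-directed layout with node size proportional to prevalence and edge
#' width proportional to phi squared (isolated nodes are drawn too).
#'
#' @param x A [build_network()] result.
#' @param size_scale,width_scale Positive rendering multipliers.
#' @param layout An igraph layout function.
#' @param seed Layout seed for reproducible placement.
#' @param ... Passed to `plot.igraph`.
#' @export
plot.comorbidity_network <- function(x, size_scale = 30, width_scale = 40,
                                     layout = igraph::layout_with_fr,
                                     seed = 1L, ...) {
  g <- as_igraph(x, size_scale, width_scale)
  set.seed(seed)
  igraph::plot.igraph(
    g, layout = layout(g),
    vertex.size = igraph::V(g)$size,
    edge.width = igraph::E(g)$width,
    main = sprintf("%s (density %.3f)", x$label, x$density), ...)
  invisible(x)
}
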