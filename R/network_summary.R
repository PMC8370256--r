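#' Degree ranking of proteins in an interaction network
#'
#' Computes, for each queried protein, its number of distinct neighbors
#' within the queried set (self-loops and duplicate edges are ignored) and
#' ranks proteins by decreasing degree, breaking ties lexicographically for
#' determinism. When the edge list carries confidence scores, edges below
#' `min_score` are discarded first.
#'
#' @param edges Tibble with columns `a`, `b` and optional `score` (see
#'   [read_edge_list()]).
#' @param proteins Optional character vector restricting the network to a
#'   protein set of interest (e.g. the proteins of one frame); queried
#'   proteins without any retained edge get degree 0. `NULL` uses every
#'   protein appearing in the edge list.
#' @param min_score Minimum edge confidence when a `score` column is
#'   present, default 0.4.
#' @param top_n Optionally return only the first `top_n` rows.
#' @return Tibble with columns `protein`, `degree`, ordered by decreasing
#'   degree then protein name.
#' @export
degree_rank <- function(edges, proteins = NULL, min_score = 0.4,
                        top_n = NULL) {
  if ("score" %in% names(edges)) {
    drop <- !is.na(edges$score) & edges$score < min_score
    edges <- edges[!drop, , drop = FALSE]
  }
  if (is.null(proteins)) {
    proteins <- unique(c(edges$a, edges$b))
  }
  proteins <- unique(as.character(proteins))
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                     vertices = NULL)
  g <- igraph::simplify(g)
  inside <- intersect(igraph::V(g)$name, proteins)
  sub <- igraph::induced_subgraph(g, inside)
  deg <- setNames(rep(0L, length(proteins)), proteins)
  deg[igraph::V(sub)$name] <- igraph::degree(sub)
  out <- tibble::tibble(protein = names(deg), degree = as.integer(deg))
  out <- out[order(-out$degree, out$protein), ]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}
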