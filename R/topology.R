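#' Convert a confident network to an igraph object
#'
#' All taxa of the network are kept as vertices, so families with no
#' confident interaction appear as isolated nodes.
#'
#' @param network a `confident_network`.
#' @return A directed `igraph` graph with `strength`, `sign` and `P` edge
#'   attributes.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "strength", "sign", "P")],
    directed = TRUE,
    vertices = data.frame(name = network$taxa))
}

#' Keep the k strongest interactions
#'
#' Edges are ranked by absolute strength, descending (signs encode
#' activation vs repression, not magnitude); ties are broken
#' lexicographically by (source, target). `k` larger than the edge count
#' returns the whole network, so the operation is idempotent.
#'
#' @param network a `confident_network`.
#' @param k number of edges to keep (>= 1).
#' @return A `confident_network` with at most `k` edges.
#' @export
top_k_edges <- function(network, k) {
  if (k < 1) stop("k must be >= 1")
  e <- network$edges
  ord <- order(-abs(e$strength), e$source, e$target)
  e <- e[utils::head(ord, k), , drop = FALSE]
  rownames(e) <- NULL
  out <- network
  out$edges <- e
  out
}

#' Per-node in-degree of the confident network
#' @param network a `confident_network`.
#' @return Named integer vector (count of incoming edges; isolated taxa 0).
#' @export
in_degree <- function(network) {
  igraph::degree(as_igraph(network), mode = "in")
}

#' Per-node out-degree of the confident network
#' @param network a `confident_network`.
#' @return Named integer vector.
#' @export
out_degree <- function(network) {
  igraph::degree(as_igraph(network), mode = "out")
}

#' Directed betweenness centrality
#'
#' Unweighted shortest-path betweenness on the directed graph: the number of
#' shortest paths between ordered pairs of other nodes passing through each
#' node, with fractional credit shared among tied shortest paths. Raw
#' (unnormalized) counts.
#'
#' @param network a `confident_network`.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(network) {
  igraph::betweenness(as_igraph(network), directed = TRUE, weights = NA,
                      normalized = FALSE)
}

#' Eigenvector centrality by power iteration
#'
#' Computed on the symmetrized, unweighted adjacency (an interaction in
#' either direction links the pair), iterating v <- A v with sup-norm
#' normalization until the largest componentwise change falls below `tol`.
#' Scores are scaled so the maximum is 1. In a disconnected graph, nodes
#' outside the dominant component may legitimately score ~0. A graph with no
#' edges returns all zeros.
#'
#' @param network a `confident_network`.
#' @param max_iter iteration cap (default 1000).
#' @param tol convergence tolerance on the max componentwise change
#'   (default 1e-9).
#' @return Named numeric vector in \[0,1\].
#' @export
eigenvector_centrality <- function(network, max_iter = 1000, tol = 1e-9) {
  n <- length(network$taxa)
  if (n == 0) stop("network has no nodes")
  A <- matrix(0, n, n, dimnames = list(network$taxa, network$taxa))
  if (nrow(network$edges)) {
    idx <- cbind(match(network$edges$source, network$taxa),
                 match(network$edges$target, network$taxa))
    A[idx] <- 1
    A <- pmax(A, t(A))  # symmetrize, unweighted
  }
  if (all(A == 0)) return(stats::setNames(numeric(n), network$taxa))
  v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    # +v shifts the spectrum by one so bipartite graphs cannot oscillate;
    # the dominant eigenvector is unchanged
    w <- drop(A %*% v) + v
    w <- w / max(w)
    if (max(abs(w - v)) < tol) {
      return(stats::setNames(w, network$taxa))
    }
    v <- w
  }
  stop("power iteration did not converge within ", max_iter, " iterations")
}

#' Ranked influential-taxon report
#'
#' All three centralities per taxon, sorted by eigenvector centrality
#' (descending, ties by label). Taxa that influence almost nobody while
#' being widely influenced are flagged via `low_out_degree`
#' (out-degree <= `low_out_cutoff`).
#'
#' @param network a `confident_network`.
#' @param top_n optionally keep only the first `top_n` rows.
#' @param low_out_cutoff out-degree at or below which a taxon is flagged
#'   (default 1).
#' @param ... passed to [eigenvector_centrality()].
#' @return data.frame with `taxon`, `in_degree`, `out_degree`,
#'   `betweenness`, `eigenvector`, `low_out_degree`.
#' @export
influential_report <- function(network, top_n = NULL, low_out_cutoff = 1,
                               ...) {
  ind <- in_degree(network)
  outd <- out_degree(network)
  btw <- betweenness_centrality(network)
  eig <- eigenvector_centrality(network, ...)
  tx <- network$taxa
  df <- data.frame(taxon = tx,
                   in_degree = as.integer(ind[tx]),
                   out_degree = as.integer(outd[tx]),
                   betweenness = unname(btw[tx]),
                   eigenvector = unname(eig[tx]),
                   low_out_degree = unname(outd[tx]) <= low_out_cutoff,
                   row.names = NULL)
  df <- df[order(-df$eigenvector, df$taxon), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(top_n)) df <- utils::head(df, top_n)
  df
}

#' Export a confident network to GraphML
#'
#' Node attributes carry all three centralities; edge attributes carry
#' strength, sign and P.
#'
#' @param network a `confident_network`.
#' @param path output `.graphml` path.
#' @export
export_graphml <- function(network, path) {
  g <- as_igraph(network)
  rep <- influential_report(network)
  rep <- rep[match(igraph::V(g)$name, rep$taxon), ]
  g <- igraph::set_vertex_attr(g, "in_degree", value = rep$in_degree)
  g <- igraph::set_vertex_attr(g, "betweenness", value = rep$betweenness)
  g <- igraph::set_vertex_attr(g, "eigenvector", value = rep$eigenvector)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a confident network to GEXF 1.2
#'
#' Minimal writer covering node centrality attributes and signed edge
#' weights, sufficient for import into Gephi-like tools.
#'
#' @param network a `confident_network`.
#' @param path output `.gexf` path.
#' @export
export_gexf <- function(network, path) {
  rep <- influential_report(network)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  nodes <- sprintf(
    paste0('      <node id="%s" label="%s">\n',
           '        <attvalues><attvalue for="0" value="%d"/>',
           '<attvalue for="1" value="%.10g"/>',
           '<attvalue for="2" value="%.10g"/></attvalues>\n',
           '      </node>'),
    esc(rep$taxon), esc(rep$taxon), rep$in_degree, rep$betweenness,
    rep$eigenvector)
  e <- network$edges
  edges <- if (nrow(e)) sprintf(
    paste0('      <edge id="%d" source="%s" target="%s" weight="%.10g">\n',
           '        <attvalues><attvalue for="3" value="%s"/>',
           '<attvalue for="4" value="%.10g"/></attvalues>\n',
           '      </edge>'),
    seq_len(nrow(e)) - 1L, esc(e$source), esc(e$target), abs(e$strength),
    e$sign, e$P) else character(0)
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    sprintf('  <graph defaultedgetype="directed" label="%s">',
            esc(network$condition)),
    '    <attributes class="node">',
    '      <attribute id="0" title="in_degree" type="integer"/>',
    '      <attribute id="1" title="betweenness" type="double"/>',
    '      <attribute id="2" title="eigenvector" type="double"/>',
    '    </attributes>',
    '    <attributes class="edge">',
    '      <attribute id="3" title="sign" type="string"/>',
    '      <attribute id="4" title="P" type="double"/>',
    '    </attributes>',
    '    <nodes>', nodes, '    </nodes>',
    '    <edges>', edges, '    </edges>',
    '  </graph>', '</gexf>')
  writeLines(xml, path)
  invisible(path)
}
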