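#' Topology metrics of a (sub)network
#'
#' One row of network topology descriptors: node and edge counts, number of
#' positive edges, average degree (`2E / N`), mean local clustering
#' coefficient (nodes of degree < 2 contribute 0), average shortest-path
#' length over connected pairs only (so the metric stays finite on
#' disconnected graphs), density (`2E / (N (N - 1))`), and mean betweenness
#' centrality normalized by `(N - 1)(N - 2) / 2` so it is comparable across
#' subnetworks of different sizes. An empty graph yields zeros with
#' `is_empty = TRUE`.
#'
#' @param graph a [CoocGraph] or plain undirected igraph (for the latter,
#'   `n_positive_edges` uses the `sign` edge attribute when present and is
#'   `NA` otherwise).
#' @param graph_id label for the record; defaults to the graph's own id.
#' @return One-row data.frame with columns `graph_id`, `n_nodes`,
#'   `n_edges`, `n_positive_edges`, `avg_degree`, `clustering_coef`,
#'   `avg_path_length`, `density`, `mean_betweenness`, `is_empty`.
#' @examples
#' topologyMetrics(igraph::make_full_graph(4))
#' @export
topologyMetrics <- function(graph, graph_id = NULL) {
    if (is(graph, "CoocGraph")) {
        if (is.null(graph_id)) graph_id <- graph@graph_id
        n_pos <- sum(graph@edges$sign == "+")
        g <- graph@graph
    } else {
        g <- graph
        if (igraph::is_directed(g)) stop("graph must be undirected")
        if (is.null(graph_id)) graph_id <- "graph"
        sg <- igraph::edge_attr(g, "sign")
        n_pos <- if (!is.null(sg)) sum(sg == "+") else NA_integer_
    }
    n <- igraph::vcount(g)
    e <- igraph::ecount(g)
    if (n == 0L)
        return(data.frame(graph_id = graph_id, n_nodes = 0L, n_edges = 0L,
                          n_positive_edges = 0L, avg_degree = 0,
                          clustering_coef = 0, avg_path_length = 0,
                          density = 0, mean_betweenness = 0,
                          is_empty = TRUE))
    apl <- if (n >= 2L)
        igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    else 0
    if (!is.finite(apl)) apl <- 0   # no connected pair at all
    cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
    if (!is.finite(cc)) cc <- 0
    btw <- if (n >= 3L)
        mean(igraph::betweenness(g, directed = FALSE, normalized = TRUE))
    else 0
    data.frame(graph_id = graph_id, n_nodes = n, n_edges = e,
               n_positive_edges = n_pos, avg_degree = 2 * e / n,
               clustering_coef = cc, avg_path_length = apl,
               density = if (n >= 2L) 2 * e / (n * (n - 1)) else 0,
               mean_betweenness = btw, is_empty = e == 0L)
}

#' Extract one sample's subnetwork
#'
#' Induced subgraph of a co-occurrence network on the ASVs whose count in
#' the given sample is positive (presence = rarefied count > 0; no
#' abundance threshold). All edges with both endpoints present are kept.
#'
#' @param net a [CoocGraph].
#' @param tables the [AsvTable] (or list of tables) holding the counts the
#'   network nodes refer to.
#' @param sample_id the sample to extract.
#' @return A [CoocGraph] with `graph_id` set to the sample id.
#' @export
sampleSubnetwork <- function(net, tables, sample_id) {
    stopifnot(is(net, "CoocGraph"))
    if (is(tables, "AsvTable")) tables <- list(tables)
    cnt <- do.call(rbind, lapply(tables, counts))
    if (!sample_id %in% colnames(cnt))
        stop("unknown sample: ", sample_id)
    nodes <- igraph::V(net@graph)$name
    missing <- setdiff(nodes, rownames(cnt))
    if (length(missing))
        stop("network node(s) absent from the count tables: ",
             paste(head(missing, 5), collapse = ", "))
    present <- nodes[cnt[nodes, sample_id] > 0]
    sg <- igraph::induced_subgraph(net@graph, present)
    ed <- net@edges[net@edges$from %in% present &
                    net@edges$to %in% present, , drop = FALSE]
    rownames(ed) <- NULL
    new("CoocGraph", graph = sg, edges = ed, params = net@params,
        graph_id = sample_id)
}

.complexity_metrics <- c("n_nodes", "n_edges", "avg_degree",
                         "clustering_coef", "avg_path_length", "density",
                         "mean_betweenness")

#' Network complexity scores from topology records
#'
#' Ordination-based scalar complexity: the seven topology metrics are
#' z-scored across records (constant metrics dropped with a warning),
#' Euclidean distances are ordinated by principal coordinates (equivalent
#' to principal components in this geometry), and the first axis is the
#' complexity score, sign-oriented to correlate positively with average
#' degree (ties broken by orienting the largest-magnitude loading
#' positive).
#'
#' @param records data.frame of topology records (rows from
#'   [topologyMetrics()]), at least 3.
#' @return A [ComplexityResult]; scores are named by `graph_id` when
#'   present.
#' @export
complexityIndex <- function(records) {
    records <- as.data.frame(records)
    if (nrow(records) < 3L)
        stop("need at least 3 topology records")
    miss <- setdiff(.complexity_metrics, names(records))
    if (length(miss))
        stop("records lack metric(s): ", paste(miss, collapse = ", "))
    m <- as.matrix(records[, .complexity_metrics])
    ids <- if ("graph_id" %in% names(records))
        as.character(records$graph_id) else as.character(seq_len(nrow(m)))
    rownames(m) <- NULL
    keep <- apply(m, 2L, function(x) max(x) > min(x))
    if (!any(keep)) {
        warning("all topology metrics constant; complexity scores are 0",
                call. = FALSE)
        return(new("ComplexityResult",
                   scores = setNames(numeric(nrow(m)), ids),
                   loadings = matrix(numeric(0), 0, 0),
                   eigenvalues = numeric(0), records = records,
                   dropped = .complexity_metrics))
    }
    if (any(!keep))
        warning("dropping constant metric(s): ",
                paste(.complexity_metrics[!keep], collapse = ", "),
                call. = FALSE)
    z <- scale(m[, keep, drop = FALSE])
    ord <- pcoaOrdination(dist(z), k = min(nrow(z) - 1L, ncol(z)))
    sc <- ord$coords[, 1L]
    r <- suppressWarnings(cor(sc, m[, "avg_degree"]))
    if (is.na(r) || abs(r) < 1e-12) {
        load <- suppressWarnings(cor(z, sc))
        load[is.na(load)] <- 0
        r <- load[which.max(abs(load))]
    }
    if (r < 0) {
        sc <- -sc
        ord$coords[, 1L] <- -ord$coords[, 1L]
    }
    loadings <- suppressWarnings(cor(z, ord$coords))
    rownames(loadings) <- colnames(z)
    new("ComplexityResult", scores = setNames(sc, ids),
        loadings = loadings, eigenvalues = ord$eigenvalues,
        records = records, dropped = .complexity_metrics[!keep])
}

#' @describeIn ComplexityResult Named per-record complexity scores.
#' @param x,object a `ComplexityResult`.
#' @export
setMethod("complexityScores", "ComplexityResult", function(x) x@scores)

setMethod("show", "ComplexityResult", function(object) {
    cat(sprintf("ComplexityResult: %d records, %d axes\n",
                length(object@scores), length(object@eigenvalues)))
    cat(sprintf("  score range: [%.3f, %.3f]%s\n",
                min(object@scores), max(object@scores),
                if (length(object@dropped))
                    paste0("; dropped: ",
                           paste(object@dropped, collapse = ", "))
                else ""))
})
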