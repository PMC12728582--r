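#' Core-ASV abundance filter
#'
#' Keeps ASVs whose mean per-sample relative abundance (over all samples
#' jointly) exceeds `min_mean_rel_abund`. The default 0.5% focuses the
#' network on the core community and suppresses noise from sparse ASVs.
#'
#' @param table an [AsvTable].
#' @param min_mean_rel_abund threshold on mean relative abundance
#'   (default 0.005).
#' @return The filtered [AsvTable].
#' @export
filterCoreAsvs <- function(table, min_mean_rel_abund = 0.005) {
    stopifnot(is(table, "AsvTable"))
    m <- counts(table)
    tot <- colSums(m)
    if (any(tot == 0))
        stop("zero-total sample(s): ",
             paste(colnames(m)[tot == 0], collapse = ", "))
    rel <- sweep(m, 2L, tot, "/")
    keep <- rowMeans(rel) > min_mean_rel_abund
    table[keep, ]
}

#' Spearman correlation test for one ASV pair
#'
#' Spearman's rho with average ranks for ties and a two-sided p-value from
#' the t approximation with `n - 2` degrees of freedom. Perfect
#' correlations map to the smallest representable positive p.
#'
#' @param x,y paired count vectors over at least 5 samples.
#' @return List with `r` and `p_raw`.
#' @examples
#' spearmanEdgeTest(1:5, c(2, 1, 4, 3, 5))
#' @export
spearmanEdgeTest <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must be paired")
    if (length(x) < 5L) stop("need at least 5 paired observations")
    if (max(x) == min(x) || max(y) == min(y))
        .stop2("rhizofun_constant_vector",
               "undefined correlation: constant vector")
    r <- cor(rank(x), rank(y))
    list(r = r, p_raw = .spearman_p(r, length(x)))
}

.spearman_p <- function(r, n) {
    r <- pmin(1, pmax(-1, r))
    p <- ifelse(abs(r) >= 1, .Machine$double.xmin,
                2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2))
    pmax(p, .Machine$double.xmin)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]).
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p_values) {
    if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p_values, method = "BH")
}

#' Network construction parameters
#'
#' Defaults follow the study conventions: core filter at 0.5% mean relative
#' abundance, edges kept when `|r| > 0.70` with FDR-adjusted `p < 0.01`.
#' `adjust = "none"` tests against raw p-values (useful at desk scale,
#' where FDR control over hundreds of pairs at ten samples keeps only
#' near-perfect correlations). `positive_only = TRUE` restricts the network
#' to positive correlations; the default keeps both signs and reports the
#' positive count as a topology metric.
#'
#' @param min_mean_rel_abund core-ASV filter threshold.
#' @param r_threshold minimum `|r|` for an edge.
#' @param p_threshold maximum adjusted p for an edge.
#' @param adjust `"BH"` or `"none"`.
#' @param positive_only keep only positive correlations.
#' @return List of class `cooc_params`.
#' @export
coocParams <- function(min_mean_rel_abund = 0.005, r_threshold = 0.70,
                       p_threshold = 0.01, adjust = c("BH", "none"),
                       positive_only = FALSE) {
    adjust <- match.arg(adjust)
    stopifnot(r_threshold >= 0, r_threshold <= 1,
              p_threshold > 0, p_threshold <= 1,
              min_mean_rel_abund >= 0, min_mean_rel_abund < 1)
    structure(list(min_mean_rel_abund = min_mean_rel_abund,
                   r_threshold = r_threshold, p_threshold = p_threshold,
                   adjust = adjust, positive_only = positive_only),
              class = "cooc_params")
}

#' Build a co-occurrence network
#'
#' Core-filters each supplied table, tests every unordered pair of core
#' ASVs (cross-kingdom pairs included when both kingdoms are supplied) with
#' the Spearman t-approximation test, adjusts all tested pairs of this
#' network together (Benjamini-Hochberg by default; each network is its own
#' inference family), and keeps edges with `|r| > r_threshold` and adjusted
#' `p < p_threshold`. Nodes are the ASVs incident to at least one kept
#' edge, attributed with their kingdom; constant-count ASVs are skipped
#' with a message.
#'
#' @param tables an [AsvTable] or a list of one table per kingdom sharing
#'   an identical sample set (at least 5 samples).
#' @param params a [coocParams()] list.
#' @param graph_id optional label for the resulting graph.
#' @return A [CoocGraph].
#' @export
buildNetwork <- function(tables, params = coocParams(), graph_id = "network") {
    if (is(tables, "AsvTable")) tables <- list(tables)
    stopifnot(length(tables) >= 1L, inherits(params, "cooc_params"),
              all(vapply(tables, is, TRUE, "AsvTable")))
    tables <- lapply(tables, filterCoreAsvs, params$min_mean_rel_abund)
    samp <- sampleIDs(tables[[1L]])
    for (tb in tables[-1L])
        if (!identical(sampleIDs(tb), samp))
            stop("tables must share an identical sample set")
    if (length(samp) < 5L)
        stop("need at least 5 samples for correlation networks")
    m <- do.call(rbind, lapply(tables, counts))
    kings <- unlist(lapply(tables, function(tb)
        rep(kingdom(tb), nrow(tb))))
    names(kings) <- rownames(m)
    if (anyDuplicated(rownames(m)))
        stop("duplicate ASV ids across tables")
    constant <- apply(m, 1L, function(x) max(x) == min(x))
    if (any(constant))
        message(sum(constant), " constant ASV(s) skipped in edge tests")
    m <- m[!constant, , drop = FALSE]
    n_asv <- nrow(m)
    n <- ncol(m)
    edges <- data.frame(from = character(0), to = character(0),
                        r = numeric(0), p_raw = numeric(0),
                        p_adj = numeric(0), sign = character(0))
    if (n_asv >= 2L) {
        ranks <- t(apply(m, 1L, rank))
        cmat <- cor(t(ranks))
        iu <- which(upper.tri(cmat), arr.ind = TRUE)
        r <- cmat[iu]
        p_raw <- .spearman_p(r, n)
        p_adj <- if (params$adjust == "BH") bhAdjust(p_raw) else p_raw
        keep <- abs(r) > params$r_threshold & p_adj < params$p_threshold
        if (params$positive_only) keep <- keep & r > 0
        if (any(keep)) {
            edges <- data.frame(
                from = rownames(m)[iu[keep, 1L]],
                to = rownames(m)[iu[keep, 2L]],
                r = r[keep], p_raw = p_raw[keep], p_adj = p_adj[keep],
                sign = ifelse(r[keep] > 0, "+", "-"))
        }
    }
    nodes <- sort(unique(c(edges$from, edges$to)))
    g <- igraph::graph_from_data_frame(
        edges, directed = FALSE,
        vertices = data.frame(name = nodes,
                              kingdom = unname(kings[nodes])))
    new("CoocGraph", graph = g, edges = edges, params = unclass(params),
        graph_id = graph_id)
}

#' @describeIn CoocGraph The underlying igraph object.
#' @param x,object a `CoocGraph`.
#' @export
setMethod("networkGraph", "CoocGraph", function(x) x@graph)

#' @describeIn CoocGraph Edge table (`from`, `to`, `r`, `p_raw`, `p_adj`,
#'   `sign`).
#' @export
setMethod("networkEdges", "CoocGraph", function(x) x@edges)

#' @describeIn CoocGraph Build parameter list.
#' @export
setMethod("buildParams", "CoocGraph", function(x) x@params)

setMethod("show", "CoocGraph", function(object) {
    g <- object@graph
    kd <- igraph::vertex_attr(g, "kingdom")
    cat(sprintf("CoocGraph '%s': %d nodes, %d edges (%d positive)\n",
                object@graph_id, igraph::vcount(g), igraph::ecount(g),
                sum(object@edges$sign == "+")))
    if (length(kd))
        cat("  kingdoms:", paste(sprintf("%s=%d", names(table(kd)),
                                         table(kd)), collapse = ", "), "\n")
})
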