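.topo_order <- function(vars, edges) {
    indeg <- setNames(integer(length(vars)), vars)
    for (v in edges$to) indeg[v] <- indeg[v] + 1L
    out <- character(0)
    ready <- vars[indeg == 0L]
    while (length(ready)) {
        v <- ready[1L]; ready <- ready[-1L]
        out <- c(out, v)
        ch <- edges$to[edges$from == v]
        for (w in ch) {
            indeg[w] <- indeg[w] - 1L
            if (indeg[w] == 0L) ready <- c(ready, w)
        }
    }
    if (length(out) != length(vars))
        stop("the path diagram contains a cycle")
    out
}

.directed_paths <- function(from, to, children) {
    paths <- list()
    walk <- function(v, trail) {
        if (v == to && length(trail) > 1L) {
            paths[[length(paths) + 1L]] <<- trail
            return(invisible())
        }
        for (w in children[[v]])
            if (!w %in% trail) walk(w, c(trail, w))
    }
    walk(from, from)
    paths
}

#' Fit a piecewise path model with Fisher's C
#'
#' Piecewise structural equation modelling: every endogenous variable of an
#' acyclic directed graph is regressed on its parents after z-scoring all
#' variables, so coefficients are standardized path estimates. Model fit is
#' assessed by testing the d-separation basis set -- for each pair of
#' non-adjacent variables (with at least one endogenous member), the
#' claimed-independent pair is tested as the partial regression p-value of
#' the earlier variable in the causal order when the later one is regressed
#' on it together with the union of both variables' parents. Fisher's
#' `C = -2 * sum(log p)` follows a chi-square distribution with `2k`
#' degrees of freedom when the structure is correct (`k` claims; a
#' saturated model gives `C = 0`, `df = 0`, `p = 1`). Direct, indirect
#' (sum over directed paths of coefficient products) and total effects are
#' reported for every pair joined by a directed path.
#'
#' @param dag data.frame with columns `from` and `to` describing the
#'   directed acyclic graph (see also [readDag()]).
#' @param data samples x variables data.frame or matrix containing every
#'   DAG variable; `n` must exceed the largest parent set plus 2.
#' @return A [PathModel].
#' @examples
#' set.seed(1)
#' a <- rnorm(200); b <- 0.8 * a + rnorm(200, 0, 0.6)
#' c <- 0.6 * b + rnorm(200, 0, 0.8)
#' pm <- fitPathModel(data.frame(from = c("a", "b"), to = c("b", "c")),
#'                    data.frame(a, b, c))
#' fisherC(pm)
#' @export
fitPathModel <- function(dag, data) {
    dag <- as.data.frame(dag)
    if (!all(c("from", "to") %in% names(dag)) || !nrow(dag))
        stop("dag must be a nonempty data.frame with columns from, to")
    dag$from <- as.character(dag$from)
    dag$to <- as.character(dag$to)
    if (any(dag$from == dag$to)) stop("self-loops are not allowed")
    if (anyDuplicated(paste(dag$from, dag$to)))
        stop("duplicate paths in dag")
    vars <- unique(c(dag$from, dag$to))
    data <- as.data.frame(data)
    missing <- setdiff(vars, names(data))
    if (length(missing))
        stop("dag variable(s) absent from data: ",
             paste(missing, collapse = ", "))
    ord <- .topo_order(vars, dag)
    parents <- lapply(setNames(ord, ord),
                      function(v) dag$from[dag$to == v])
    children <- lapply(setNames(ord, ord),
                       function(v) dag$to[dag$from == v])
    n <- nrow(data)
    if (n <= max(lengths(parents)) + 2L)
        stop("too few observations for the largest parent set")
    z <- as.data.frame(scale(data[, vars, drop = FALSE]))
    if (anyNA(z)) stop("variables must be non-constant and complete")

    coefs <- data.frame(response = character(0), predictor = character(0),
                        estimate = numeric(0), std_error = numeric(0),
                        p = numeric(0))
    r2 <- numeric(0)
    for (v in ord) {
        pa <- parents[[v]]
        if (!length(pa)) next
        X <- as.matrix(z[, pa, drop = FALSE])
        if (length(pa) > 1L && kappa(crossprod(X)) > 1e8)
            stop("collinear parents for '", v, "'")
        fit <- lm(z[[v]] ~ X)
        sm <- summary(fit)$coefficients
        coefs <- rbind(coefs, data.frame(
            response = v, predictor = pa,
            estimate = unname(sm[-1L, 1L]),
            std_error = unname(sm[-1L, 2L]),
            p = unname(sm[-1L, 4L])))
        r2[v] <- summary(fit)$r.squared
    }

    # d-separation basis: non-adjacent pairs with an endogenous member,
    # conditioned on the union of both variables' parents
    adj <- paste(dag$from, dag$to)
    claims <- data.frame(x = character(0), y = character(0),
                         conditioning = character(0), p = numeric(0))
    pos <- setNames(seq_along(ord), ord)
    for (i in seq_along(ord)) for (j in seq_along(ord)) {
        if (i >= j) next
        x <- ord[i]; y <- ord[j]
        if (paste(x, y) %in% adj || paste(y, x) %in% adj) next
        if (!length(parents[[x]]) && !length(parents[[y]])) next
        cond <- setdiff(union(parents[[x]], parents[[y]]), c(x, y))
        X <- as.matrix(z[, c(x, cond), drop = FALSE])
        fit <- lm(z[[y]] ~ X)
        p <- summary(fit)$coefficients[2L, 4L]
        claims <- rbind(claims, data.frame(
            x = x, y = y,
            conditioning = paste(cond, collapse = ","), p = p))
    }
    k <- nrow(claims)
    C <- if (k) -2 * sum(log(pmax(claims$p, .Machine$double.xmin))) else 0
    fisher <- list(C = C, df = 2L * k,
                   p = if (k) pchisq(C, 2L * k, lower.tail = FALSE) else 1)

    coef_of <- function(a, b) {
        hit <- coefs$response == b & coefs$predictor == a
        if (any(hit)) coefs$estimate[hit] else 0
    }
    effects <- data.frame(from = character(0), to = character(0),
                          direct = numeric(0), indirect = numeric(0),
                          total = numeric(0))
    for (a in ord) for (b in ord) {
        if (a == b) next
        paths <- .directed_paths(a, b, children)
        if (!length(paths)) next
        direct <- coef_of(a, b)
        indirect <- 0
        for (p in paths) {
            if (length(p) == 2L) next
            prod_c <- 1
            for (s in seq_len(length(p) - 1L))
                prod_c <- prod_c * coef_of(p[s], p[s + 1L])
            indirect <- indirect + prod_c
        }
        effects <- rbind(effects, data.frame(
            from = a, to = b, direct = direct, indirect = indirect,
            total = direct + indirect))
    }
    new("PathModel", edges = dag[, c("from", "to")], coefficients = coefs,
        claims = claims, fisherC = fisher, effects = effects,
        rsquared = r2, n = as.integer(n))
}

#' @describeIn PathModel Fisher's C list (`C`, `df`, `p`).
#' @param x,object a `PathModel`.
#' @export
setMethod("fisherC", "PathModel", function(x) x@fisherC)

#' @describeIn PathModel Standardized path coefficient table.
#' @export
setMethod("pathCoefficients", "PathModel", function(x) x@coefficients)

#' @describeIn PathModel Direct/indirect/total effect table.
#' @export
setMethod("pathEffects", "PathModel", function(x) x@effects)

setMethod("show", "PathModel", function(object) {
    fc <- object@fisherC
    cat(sprintf("PathModel: %d paths, %d independence claims, n = %d\n",
                nrow(object@edges), nrow(object@claims), object@n))
    cat(sprintf("  Fisher's C = %.3f, df = %d, p = %.3f\n",
                fc$C, fc$df, fc$p))
    for (i in seq_len(nrow(object@coefficients))) {
        co <- object@coefficients[i, ]
        cat(sprintf("  %s -> %s: %.3f (p = %.3g)\n", co$predictor,
                    co$response, co$estimate, co$p))
    }
})
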