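#' Bray-Curtis dissimilarity between samples
#'
#' `sum(|x - y|) / sum(x + y)` over features, in \[0, 1\] for nonnegative
#' profiles. Accepts an [AsvTable] (samples are compared on their count
#' profiles) or a samples-in-rows numeric matrix.
#'
#' @param x an [AsvTable] or a samples x features matrix.
#' @return A `dist` object over samples.
#' @export
brayCurtis <- function(x) {
    m <- if (is(x, "AsvTable")) t(counts(x)) else as.matrix(x)
    if (any(m < 0)) stop("Bray-Curtis requires nonnegative values")
    vegan::vegdist(m, method = "bray")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a distance matrix. Axes come out centered
#' and eigenvalue-sorted; negative eigenvalues (possible for non-Euclidean
#' dissimilarities such as Bray-Curtis) are dropped and their magnitudes
#' reported.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param k number of axes requested; capped at the number of positive
#'   eigenvalues.
#' @return List with `coords` (samples x axes), `eigenvalues` (positive,
#'   non-increasing, one per returned axis), `all_eigenvalues`, and
#'   `negative_eigenvalues` (magnitudes of dropped negative eigenvalues).
#' @export
pcoaOrdination <- function(d, k = 2L) {
    m <- .as_dist_matrix(d)
    n <- nrow(m)
    if (n < 2L) stop("need at least two samples")
    k <- min(k, n - 1L)
    fit <- suppressWarnings(cmdscale(m, k = k, eig = TRUE))
    eig <- fit$eig
    pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
    pts <- fit$points
    keep <- min(ncol(pts), length(pos))
    if (keep < 1L) stop("no positive eigenvalues; distances are degenerate")
    pts <- pts[, seq_len(keep), drop = FALSE]
    colnames(pts) <- paste0("Axis", seq_len(keep))
    rownames(pts) <- rownames(m)
    list(coords = pts, eigenvalues = pos[seq_len(keep)],
         all_eigenvalues = eig,
         negative_eigenvalues = abs(eig[eig < 0]))
}

#' Permutational multivariate analysis of variance
#'
#' Single-factor PERMANOVA on a distance matrix: the total sum of squared
#' distances is partitioned into among- and within-group components, the
#' pseudo-F statistic is `(SSA / (a - 1)) / (SSW / (n - a))`, and its
#' p-value is obtained by permuting group labels whole:
#' `p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1)`.
#'
#' Matches `vegan::adonis2` for the one-factor design in pseudo-F and R2.
#'
#' @param d `dist` or symmetric distance matrix over samples.
#' @param groups group label per sample; at least two groups, each with at
#'   least two samples.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return List with `pseudo_F`, `p`, `R2`, `df` (among, within), `n_perm`.
#' @export
permanovaTest <- function(d, groups, n_perm = 999L, seed = NULL) {
    m <- .as_dist_matrix(d)
    n <- nrow(m)
    groups <- as.factor(groups)
    if (length(groups) != n)
        stop("groups must have one label per sample")
    tab <- table(groups)
    if (length(tab) < 2L)
        stop("need at least two groups")
    if (any(tab < 2L))
        stop("singleton group(s): ",
             paste(names(tab)[tab < 2L], collapse = ", "))
    .check_seed(seed)
    D2 <- m^2
    a <- length(tab)
    sst <- sum(D2) / (2 * n)
    ssw_of <- function(g) {
        s <- 0
        for (lev in levels(g)) {
            idx <- which(g == lev)
            s <- s + sum(D2[idx, idx]) / (2 * length(idx))
        }
        s
    }
    f_of <- function(ssw) ((sst - ssw) / (a - 1)) / (ssw / (n - a))
    ssw <- ssw_of(groups)
    f_obs <- f_of(ssw)
    ge <- 0L
    for (i in seq_len(n_perm)) {
        fp <- f_of(ssw_of(groups[sample.int(n)]))
        if (fp >= f_obs) ge <- ge + 1L
    }
    list(pseudo_F = f_obs, p = (ge + 1L) / (n_perm + 1L),
         R2 = (sst - ssw) / sst, df = c(among = a - 1L, within = n - a),
         n_perm = as.integer(n_perm))
}

#' @importFrom stats rbinom
NULL
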