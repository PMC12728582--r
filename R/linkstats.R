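#' Pairwise correlation matrix with p-values
#'
#' Pearson or Spearman correlations between the columns of a per-sample
#' feature table, with two-sided p-values from the t approximation on
#' `n - 2` degrees of freedom. Constant columns yield `NA` entries and a
#' warning rather than a silent zero.
#'
#' @param vars samples x variables numeric matrix or data.frame (>= 4
#'   samples).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with matrices `r` and `p`, and `n`.
#' @export
correlationMatrix <- function(vars, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    m <- as.matrix(vars)
    if (nrow(m) < 4L) stop("need at least 4 samples")
    con <- apply(m, 2L, function(x) max(x) == min(x))
    if (any(con))
        warning("constant column(s) flagged undefined: ",
                paste(colnames(m)[con], collapse = ", "), call. = FALSE)
    if (method == "spearman") m <- apply(m, 2L, rank)
    n <- nrow(m)
    r <- suppressWarnings(cor(m))
    r[con, ] <- NA; r[, con] <- NA
    diag(r)[!con] <- 1
    tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-tt, n - 2)
    p[abs(r) >= 1] <- .Machine$double.xmin
    diag(p) <- NA
    list(r = r, p = p, n = n)
}

#' Simple least-squares regression
#'
#' Ordinary least squares of `y` on `x` with the slope's two-sided t-test
#' and `R2 = 1 - SSres / SStot`.
#'
#' @param x,y numeric vectors of at least 3 paired points with positive
#'   variance.
#' @return List with `slope`, `intercept`, `r2`, `p_slope`, `n`.
#' @export
olsFit <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must be paired")
    if (length(x) < 3L) stop("need at least 3 points")
    if (var(x) == 0) stop("degenerate predictor: var(x) = 0")
    if (var(y) == 0)
        .stop2("rhizofun_degenerate_response",
               "degenerate response: var(y) = 0")
    fit <- lm(y ~ x)
    sm <- summary(fit)
    list(slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         r2 = sm$r.squared,
         p_slope = sm$coefficients[2L, 4L],
         n = length(x))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the vectorized upper triangles, with a one-sided
#' permutation p-value obtained by jointly permuting the rows and columns
#' of the second matrix:
#' `p = (#\{r_perm >= r_obs\} + 1) / (n_perm + 1)`.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantelTest <- function(d1, d2, n_perm = 999L, seed = NULL) {
    m1 <- .as_dist_matrix(d1, "d1")
    m2 <- .as_dist_matrix(d2, "d2")
    if (nrow(m1) != nrow(m2))
        stop("distance matrices must cover the same samples")
    n <- nrow(m1)
    ut <- upper.tri(m1)
    v1 <- m1[ut]
    r_obs <- cor(v1, m2[ut])
    .check_seed(seed)
    ge <- 0L
    for (i in seq_len(n_perm)) {
        idx <- sample.int(n)
        if (cor(v1, m2[idx, idx][ut]) >= r_obs) ge <- ge + 1L
    }
    list(r = r_obs, p = (ge + 1L) / (n_perm + 1L),
         n_perm = as.integer(n_perm))
}

#' Random-forest variable importance
#'
#' Random-forest regression of a response on a per-sample feature table;
#' importance is the percent increase in out-of-bag mean squared error when
#' a predictor is permuted (%IncMSE). Deterministic given `seed`.
#'
#' @param features samples x predictors data.frame or matrix (>= 2
#'   predictors, >= 8 samples).
#' @param response numeric response vector.
#' @param n_trees trees to grow (default 500).
#' @param seed optional integer seed.
#' @return Named numeric vector of %IncMSE per predictor.
#' @export
rfImportance <- function(features, response, n_trees = 500L, seed = NULL) {
    features <- as.data.frame(features)
    if (ncol(features) < 2L) stop("need at least 2 predictors")
    if (nrow(features) < 8L) stop("need at least 8 samples")
    if (length(response) != nrow(features))
        stop("response must match the feature rows")
    if (max(response) == min(response))
        stop("constant response")
    .check_seed(seed)
    rf <- randomForest::randomForest(x = features, y = response,
                                     ntree = n_trees, importance = TRUE)
    imp <- randomForest::importance(rf, type = 1L, scale = TRUE)
    setNames(imp[, 1L], rownames(imp))
}
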