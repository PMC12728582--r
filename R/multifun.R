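#' Min-max standardization
#'
#' `STD = (X - X_min) / (X_max - X_min)` elementwise, mapping the minimum of
#' a variable over samples to 0 and the maximum to 1.
#'
#' @param x numeric vector of at least two values.
#' @return Vector of the same length in \[0, 1\].
#' @examples
#' standardizeMinmax(c(2, 4, 6))
#' @export
standardizeMinmax <- function(x) {
    if (length(x) < 2L)
        stop("need at least two values")
    if (anyNA(x) || any(!is.finite(x)))
        stop("values must be finite")
    rng <- range(x)
    if (rng[1L] == rng[2L])
        .degenerate_range("min-max standardization")
    (x - rng[1L]) / (rng[2L] - rng[1L])
}

.std_matrix <- function(fm, degenerate = c("abort", "drop")) {
    degenerate <- match.arg(degenerate)
    m <- fmValues(fm)
    con <- apply(m, 2L, function(col) max(col) == min(col))
    if (any(con)) {
        if (degenerate == "abort")
            .stop2("rhizofun_degenerate_range",
                   "constant function column(s): %s (set degenerate = 'drop' to discard)",
                   paste(colnames(m)[con], collapse = ", "))
        warning("dropping constant function column(s): ",
                paste(colnames(m)[con], collapse = ", "), call. = FALSE)
        m <- m[, !con, drop = FALSE]
    }
    apply(m, 2L, standardizeMinmax)
}

#' Average multifunctionality index
#'
#' Min-max standardizes every function column and averages the standardized
#' values per sample. Constant function columns abort by default (silently
#' dropping them would change the AMI denominator invisibly); pass
#' `degenerate = "drop"` to discard them with a warning.
#'
#' @param fm a [FunctionMatrix].
#' @param degenerate `"abort"` (default) or `"drop"` behaviour for constant
#'   columns.
#' @return A [MultifunResult] with the `std` matrix and `ami` filled.
#' @examples
#' m <- matrix(runif(36), 9, 4,
#'             dimnames = list(paste0("s", 1:9), c("SOC", "TN", "AP", "Ure")))
#' res <- computeAMI(FunctionMatrix(m))
#' ami(res)
#' @export
computeAMI <- function(fm, degenerate = c("abort", "drop")) {
    std <- .std_matrix(fm, degenerate)
    new("MultifunResult", std = std,
        ami = rowMeans(std),
        groupAmi = matrix(numeric(0), nrow(std), 0,
                          dimnames = list(rownames(std), NULL)),
        pmi = matrix(numeric(0), nrow(std), 0,
                     dimnames = list(rownames(std), NULL)),
        pmiEigenvalues = numeric(0), groupMap = list())
}

#' Default carbon / nitrogen / phosphorus function groups
#'
#' Groups the canonical twelve functions by the element cycle they report
#' on: carbon (SOC, MBC, SSC), nitrogen (TN, AN, NN, MBN, Ure) and
#' phosphorus (TP, AP, MBP, ALP). Group membership is a configurable
#' convention, not a measurement.
#'
#' @return Named list of function-name vectors.
#' @export
defaultFunctionGroups <- function() {
    list(AMI.C = c("SOC", "MBC", "SSC"),
         AMI.N = c("TN", "AN", "NN", "MBN", "Ure"),
         AMI.P = c("TP", "AP", "MBP", "ALP"))
}

#' Group-wise multifunctionality indices
#'
#' Per-sample mean of the standardized function values restricted to each
#' named group (for example the element-cycle groups of
#' [defaultFunctionGroups()]).
#'
#' @param fm a [FunctionMatrix].
#' @param group_map named list mapping group name to function names; every
#'   function must exist in `fm` and every group must be nonempty.
#' @param degenerate behaviour for constant columns, see [computeAMI()].
#' @return samples x groups numeric matrix.
#' @export
computeGroupAMI <- function(fm, group_map = defaultFunctionGroups(),
                            degenerate = c("abort", "drop")) {
    std <- .std_matrix(fm, degenerate)
    if (!length(group_map) || is.null(names(group_map)))
        stop("group_map must be a nonempty named list")
    out <- matrix(NA_real_, nrow(std), length(group_map),
                  dimnames = list(rownames(std), names(group_map)))
    for (g in names(group_map)) {
        fns <- group_map[[g]]
        if (!length(fns))
            stop("group '", g, "' is empty")
        unknown <- setdiff(fns, colnames(std))
        if (length(unknown))
            stop("group '", g, "' names unknown function(s): ",
                 paste(unknown, collapse = ", "))
        out[, g] <- rowMeans(std[, fns, drop = FALSE])
    }
    out
}

#' Principal-coordinate multifunctionality index
#'
#' Computes Bray-Curtis distances between the samples' min-max standardized
#' function profiles (standardized values lie in \[0, 1\], so the distance
#' is well defined across units) and extracts the first `axes` principal
#' coordinates. Each axis is sign-oriented so that its correlation with the
#' AMI is non-negative (principal-coordinate signs are arbitrary; this makes
#' PMI.1 increase with overall multifunctionality); exact ties are broken by
#' orienting the largest-magnitude function loading positive. Negative
#' eigenvalues of the non-Euclidean Bray-Curtis geometry are dropped with a
#' message.
#'
#' @param fm a [FunctionMatrix].
#' @param axes number of axes requested (default 5); reduced with a message
#'   when fewer samples or positive eigenvalues are available.
#' @param degenerate behaviour for constant columns, see [computeAMI()].
#' @return List with `pmi` (samples x axes score matrix, columns `PMI.1`,
#'   ...), `eigenvalues`, and `negative_eigenvalues` (magnitudes dropped).
#' @export
computePMI <- function(fm, axes = 5L, degenerate = c("abort", "drop")) {
    std <- .std_matrix(fm, degenerate)
    zero <- rowSums(std) == 0
    if (any(zero))
        stop("Bray-Curtis undefined: standardized profile is all zero for ",
             "sample(s) ", paste(rownames(std)[zero], collapse = ", "))
    if (nrow(std) < axes + 1L) {
        axes <- nrow(std) - 1L
        message("fewer samples than requested axes; returning ", axes,
                " axes")
    }
    d <- vegan::vegdist(std, method = "bray")
    ord <- pcoaOrdination(d, k = axes)
    ami_v <- rowMeans(std)
    sc <- ord$coords
    for (j in seq_len(ncol(sc))) {
        r <- suppressWarnings(cor(sc[, j], ami_v))
        if (is.na(r) || abs(r) < 1e-12) {
            load <- suppressWarnings(cor(std, sc[, j]))
            load[is.na(load)] <- 0
            r <- load[which.max(abs(load))]
        }
        if (r < 0) sc[, j] <- -sc[, j]
    }
    colnames(sc) <- paste0("PMI.", seq_len(ncol(sc)))
    list(pmi = sc, eigenvalues = ord$eigenvalues,
         negative_eigenvalues = ord$negative_eigenvalues)
}

#' All multifunctionality indices at once
#'
#' Convenience wrapper assembling the single-function standardized matrix,
#' the AMI, the group AMIs and the PMI axes into one [MultifunResult].
#'
#' @inheritParams computePMI
#' @param group_map see [computeGroupAMI()].
#' @return A [MultifunResult].
#' @export
multifunIndices <- function(fm, group_map = defaultFunctionGroups(),
                            axes = 5L, degenerate = c("abort", "drop")) {
    base <- computeAMI(fm, degenerate)
    grp <- computeGroupAMI(fm, group_map, degenerate)
    pm <- computePMI(fm, axes, degenerate)
    new("MultifunResult", std = base@std, ami = base@ami, groupAmi = grp,
        pmi = pm$pmi, pmiEigenvalues = pm$eigenvalues,
        groupMap = group_map)
}

#' @describeIn MultifunResult Per-sample averaged multifunctionality index.
#' @param x,object a `MultifunResult`.
#' @export
setMethod("ami", "MultifunResult", function(x) x@ami)

#' @describeIn MultifunResult Samples x groups AMI matrix.
#' @export
setMethod("groupAMI", "MultifunResult", function(x) x@groupAmi)

#' @describeIn MultifunResult Samples x axes PMI score matrix.
#' @export
setMethod("pmi", "MultifunResult", function(x) x@pmi)

#' @describeIn MultifunResult Standardized single-function matrix.
#' @export
setMethod("stdFunctions", "MultifunResult", function(x) x@std)

#' @describeIn MultifunResult Eigenvalues of the retained PMI axes.
#' @export
setMethod("pmiEigenvalues", "MultifunResult", function(x) x@pmiEigenvalues)

#' @describeIn MultifunResult Sample identifiers.
#' @export
setMethod("sampleIDs", "MultifunResult", function(x) rownames(x@std))

setMethod("show", "MultifunResult", function(object) {
    cat(sprintf("MultifunResult: %d samples, %d functions\n",
                nrow(object@std), ncol(object@std)))
    cat(sprintf("  AMI range: [%.3f, %.3f]; PMI axes: %d; groups: %s\n",
                min(object@ami), max(object@ami), ncol(object@pmi),
                if (ncol(object@groupAmi))
                    paste(colnames(object@groupAmi), collapse = ", ")
                else "none"))
})
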