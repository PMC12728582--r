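#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats cor cmdscale dist lm pchisq pf pnorm pt quantile rnorm
#'   runif sd setNames var complete.cases coef p.adjust
#' @importFrom utils read.delim write.table head
NULL

setOldClass("igraph")

#' ASV count table for one kingdom
#'
#' `AsvTable` holds counts of amplicon sequence variants (rows) by samples
#' (columns) for a single kingdom, together with an optional taxonomy lineage
#' per ASV. It extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class],
#' so all of its subsetting and annotation machinery applies; the count
#' matrix lives in the `"counts"` assay, lineages in `rowData(x)$taxonomy`,
#' and the kingdom in `metadata(x)$kingdom`.
#'
#' Validity requires non-negative whole-number counts, unique ASV and sample
#' identifiers, and a kingdom of `"bacteria"` or `"fungi"`.
#'
#' @seealso [AsvTable()] for construction, [readAsvTable()] for file input.
#' @aliases AsvTable-class
#' @exportClass AsvTable
setClass("AsvTable", contains = "SummarizedExperiment")

setValidity("AsvTable", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (!is.numeric(m))
            msg <- c(msg, "counts must be numeric")
        else {
            if (anyNA(m) || any(!is.finite(m)))
                msg <- c(msg, "counts must be finite and non-missing")
            else {
                if (any(m < 0))
                    msg <- c(msg, "counts must be non-negative")
                if (any(m != floor(m)))
                    msg <- c(msg, "counts must be whole numbers")
            }
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "ASV ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    kd <- S4Vectors::metadata(object)$kingdom
    if (is.null(kd) || !kd %in% c("bacteria", "fungi"))
        msg <- c(msg, "metadata kingdom must be 'bacteria' or 'fungi'")
    if (length(msg)) msg else TRUE
})

#' Matrix of measured soil functions
#'
#' Samples in rows, functions in columns, values in the units they were
#' measured in. The canonical function set is the twelve carbon, nitrogen
#' and phosphorus pool, microbial-biomass and enzyme-activity variables
#' returned by [soilFunctionNames()]; other function sets are accepted.
#'
#' @slot values numeric matrix, samples x functions, no missing cells.
#' @seealso [FunctionMatrix()], [readFunctionMatrix()], [computeAMI()].
#' @aliases FunctionMatrix-class
#' @exportClass FunctionMatrix
setClass("FunctionMatrix", representation(values = "matrix"))

setValidity("FunctionMatrix", function(object) {
    m <- object@values
    msg <- character()
    if (!is.numeric(m))
        msg <- c(msg, "values must be numeric")
    else if (anyNA(m) || any(!is.finite(m)))
        msg <- c(msg, "values must be finite with no missing cells")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        msg <- c(msg, "sample ids must be present and unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        msg <- c(msg, "function names must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Soil multifunctionality indices
#'
#' Container for the three multifunctionality indices computed from a
#' [FunctionMatrix]: the per-sample single-function (min-max standardized)
#' matrix, the averaged multifunctionality index (AMI), element-cycle group
#' AMIs, and the principal-coordinate multifunctionality axes (PMI) with
#' their eigenvalues.
#'
#' @slot std samples x functions matrix of min-max standardized values in
#'   \[0, 1\].
#' @slot ami named per-sample numeric vector, the row means of `std`.
#' @slot groupAmi samples x groups matrix of per-group means (may have zero
#'   columns if groups were not requested).
#' @slot pmi samples x axes matrix of principal-coordinate scores.
#' @slot pmiEigenvalues eigenvalues of the retained PMI axes.
#' @slot groupMap named list mapping group name to function names.
#' @aliases MultifunResult-class
#' @exportClass MultifunResult
setClass("MultifunResult",
    representation(std = "matrix", ami = "numeric", groupAmi = "matrix",
                   pmi = "matrix", pmiEigenvalues = "numeric",
                   groupMap = "list"))

setValidity("MultifunResult", function(object) {
    msg <- character()
    if (length(object@ami) && (min(object@ami) < -1e-12 ||
                               max(object@ami) > 1 + 1e-12))
        msg <- c(msg, "ami must lie in [0, 1]")
    if (length(object@std) && (min(object@std) < -1e-12 ||
                               max(object@std) > 1 + 1e-12))
        msg <- c(msg, "std must lie in [0, 1]")
    if (ncol(object@pmi) && length(object@pmiEigenvalues) &&
        is.unsorted(rev(object@pmiEigenvalues), strictly = FALSE))
        msg <- c(msg, "pmi eigenvalues must be non-increasing")
    if (length(msg)) msg else TRUE
})

#' Co-occurrence network
#'
#' An undirected correlation network over core ASVs. Nodes carry a `kingdom`
#' attribute; edges carry the Spearman correlation `r`, the raw and
#' FDR-adjusted p-values, and a sign. The filter settings used to build the
#' network are kept in `buildParams(x)`.
#'
#' @slot graph an [igraph][igraph::igraph-package] undirected simple graph.
#' @slot edges data.frame with columns `from`, `to`, `r`, `p_raw`, `p_adj`,
#'   `sign`.
#' @slot params list of build parameters (see [coocParams()]).
#' @slot graph_id single character label (the sample id for subnetworks).
#' @seealso [buildNetwork()], [sampleSubnetwork()], [topologyMetrics()].
#' @aliases CoocGraph-class
#' @exportClass CoocGraph
setClass("CoocGraph",
    representation(graph = "igraph", edges = "data.frame", params = "list",
                   graph_id = "character"))

setValidity("CoocGraph", function(object) {
    g <- object@graph
    msg <- character()
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (igraph::vcount(g) && igraph::any_loop(g))
        msg <- c(msg, "graph must not contain self-loops")
    if (igraph::vcount(g) && igraph::any_multiple(g))
        msg <- c(msg, "graph must not contain duplicate edges")
    if (nrow(object@edges) != igraph::ecount(g))
        msg <- c(msg, "edge table and graph disagree on edge count")
    ed <- object@edges
    need <- c("from", "to", "r", "p_raw", "p_adj", "sign")
    if (!all(need %in% names(ed)))
        msg <- c(msg, "edge table must have columns from/to/r/p_raw/p_adj/sign")
    else if (nrow(ed) && !all(ed$sign %in% c("+", "-")))
        msg <- c(msg, "edge signs must be '+' or '-'")
    if (length(msg)) msg else TRUE
})

#' Network complexity ordination
#'
#' Result of ordinating per-subnetwork topology records: the per-subnetwork
#' complexity score (axis 1, oriented to correlate positively with average
#' degree), axis loadings, eigenvalues, and the input records.
#'
#' @slot scores named numeric vector of complexity scores (centered at 0).
#' @slot loadings correlations of each retained topology metric with each
#'   ordination axis.
#' @slot eigenvalues positive eigenvalues of the ordination.
#' @slot records the topology records the ordination was computed from.
#' @slot dropped names of metrics dropped because they were constant.
#' @seealso [complexityIndex()].
#' @aliases ComplexityResult-class
#' @exportClass ComplexityResult
setClass("ComplexityResult",
    representation(scores = "numeric", loadings = "matrix",
                   eigenvalues = "numeric", records = "data.frame",
                   dropped = "character"))

#' Piecewise path model
#'
#' A fitted piecewise structural equation model: each endogenous variable of
#' an acyclic directed graph is regressed on its parents (on z-scored data,
#' so coefficients are standardized), the d-separation independence claims
#' are tested, and overall fit is summarized by Fisher's C.
#'
#' @slot edges data.frame with columns `from`, `to` (the DAG).
#' @slot coefficients per-path standardized estimates with standard errors
#'   and p-values.
#' @slot claims tested independence claims with their p-values.
#' @slot fisherC list with elements `C`, `df`, `p`.
#' @slot effects direct, indirect and total effects for every ordered pair
#'   connected by at least one directed path.
#' @slot rsquared named R-squared per endogenous variable.
#' @slot n number of observations.
#' @seealso [fitPathModel()].
#' @aliases PathModel-class
#' @exportClass PathModel
setClass("PathModel",
    representation(edges = "data.frame", coefficients = "data.frame",
                   claims = "data.frame", fisherC = "list",
                   effects = "data.frame", rsquared = "numeric",
                   n = "integer"))
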