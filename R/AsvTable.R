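#' Construct an ASV count table
#'
#' @param counts numeric matrix of non-negative whole-number counts, ASVs in
#'   rows and samples in columns, with row and column names.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param taxonomy optional named character vector of semicolon-separated
#'   lineages (`domain;phylum;...;genus`, possibly truncated); every name
#'   must be an ASV id of `counts`.
#'
#' @return An [AsvTable] object.
#' @examples
#' m <- matrix(c(3, 0, 0, 5, 1, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("ASV", 1:3), c("s1", "s2")))
#' tab <- AsvTable(m, "bacteria")
#' colSums(counts(tab))
#' @export
AsvTable <- function(counts, kingdom = c("bacteria", "fungi"),
                     taxonomy = NULL) {
    kingdom <- match.arg(kingdom)
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have ASV row names and sample column names")
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(taxonomy)) {
        if (is.null(names(taxonomy)))
            stop("taxonomy must be named by ASV id")
        bad <- setdiff(names(taxonomy), rownames(counts))
        if (length(bad))
            stop("taxonomy keys are not ASV ids: ",
                 paste(head(bad, 5), collapse = ", "))
        tx <- rep(NA_character_, nrow(counts))
        names(tx) <- rownames(counts)
        tx[names(taxonomy)] <- as.character(taxonomy)
        rd$taxonomy <- unname(tx)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd,
        metadata = list(kingdom = kingdom))
    new("AsvTable", se)
}

#' @describeIn AsvTable Count matrix (ASVs x samples).
#' @param object,x an `AsvTable`.
#' @importFrom BiocGenerics counts
#' @export counts
#' @exportMethod counts
setMethod("counts", "AsvTable", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @describeIn AsvTable Kingdom of the table.
#' @export
setMethod("kingdom", "AsvTable", function(x)
    S4Vectors::metadata(x)$kingdom)

#' @describeIn AsvTable Named lineage vector, or `NULL` when absent.
#' @export
setMethod("taxonomy", "AsvTable", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"taxonomy" %in% names(rd)) return(NULL)
    setNames(rd$taxonomy, rownames(x))
})

#' @describeIn AsvTable Sample identifiers.
#' @export
setMethod("sampleIDs", "AsvTable", function(x) colnames(x))

setMethod("show", "AsvTable", function(object) {
    cat(sprintf("AsvTable (%s): %d ASVs x %d samples\n",
                S4Vectors::metadata(object)$kingdom,
                nrow(object), ncol(object)))
    cat(sprintf("  total counts: %g; taxonomy: %s\n",
                sum(SummarizedExperiment::assay(object, "counts")),
                if (is.null(taxonomy(object))) "absent" else "present"))
})

#' Canonical soil function names
#'
#' The twelve measured soil functions used to score multifunctionality:
#' alkaline phosphatase (ALP), available phosphorus (AP), total phosphorus
#' (TP), microbial biomass phosphorus (MBP), ammonium nitrogen (AN), nitrate
#' nitrogen (NN), microbial biomass nitrogen (MBN), total nitrogen (TN),
#' urease (Ure), microbial biomass carbon (MBC), soil organic carbon (SOC),
#' and sucrase (SSC).
#'
#' @return Character vector of length 12.
#' @export
soilFunctionNames <- function() {
    c("ALP", "AP", "TP", "MBP", "AN", "NN", "MBN", "TN",
      "Ure", "MBC", "SOC", "SSC")
}

#' Construct a soil function matrix
#'
#' @param values numeric matrix, samples in rows and functions in columns,
#'   with dimnames and no missing cells.
#' @param check_names warn when the column set differs from the canonical
#'   twelve functions of [soilFunctionNames()] (user-defined sets allowed).
#' @return A [FunctionMatrix] object.
#' @export
FunctionMatrix <- function(values, check_names = TRUE) {
    values <- as.matrix(values)
    if (check_names && !is.null(colnames(values))) {
        unknown <- setdiff(colnames(values), soilFunctionNames())
        if (length(unknown))
            warning("non-canonical function names accepted: ",
                    paste(unknown, collapse = ", "), call. = FALSE)
    }
    new("FunctionMatrix", values = values)
}

#' @describeIn FunctionMatrix Numeric samples x functions matrix.
#' @param x a `FunctionMatrix`.
#' @export
setMethod("fmValues", "FunctionMatrix", function(x) x@values)

#' @describeIn FunctionMatrix Function (column) names.
#' @export
setMethod("functionNames", "FunctionMatrix", function(x) colnames(x@values))

#' @describeIn FunctionMatrix Sample (row) identifiers.
#' @export
setMethod("sampleIDs", "FunctionMatrix", function(x) rownames(x@values))

setMethod("show", "FunctionMatrix", function(object) {
    cat(sprintf("FunctionMatrix: %d samples x %d functions\n",
                nrow(object@values), ncol(object@values)))
    cat("  functions:", paste(colnames(object@values), collapse = ", "), "\n")
})

#' Validate sample metadata against the tables it describes
#'
#' Sample metadata is a plain data.frame with columns `sample_id`,
#' `treatment` and `replicate`. This helper checks that every sample of the
#' supplied tables is described, and that the design is usable for
#' inference (at least two treatments with at least two replicates each).
#'
#' @param metadata data.frame with columns `sample_id`, `treatment`,
#'   `replicate`.
#' @param ... objects with a [sampleIDs()] method whose samples must all
#'   appear in `metadata`.
#' @param inferential require >= 2 treatments and >= 2 replicates per
#'   treatment.
#' @return The metadata, invisibly, with `treatment` as a factor.
#' @export
validateMetadata <- function(metadata, ..., inferential = TRUE) {
    need <- c("sample_id", "treatment", "replicate")
    if (!all(need %in% names(metadata)))
        stop("metadata must have columns sample_id, treatment, replicate")
    if (anyDuplicated(metadata$sample_id))
        stop("duplicate sample ids in metadata")
    for (obj in list(...)) {
        missing <- setdiff(sampleIDs(obj), metadata$sample_id)
        if (length(missing))
            stop("samples absent from metadata: ",
                 paste(head(missing, 5), collapse = ", "))
    }
    metadata$treatment <- factor(metadata$treatment)
    if (inferential) {
        tab <- table(metadata$treatment)
        if (length(tab) < 2L || any(tab < 2L))
            stop("need >= 2 treatments with >= 2 replicates each")
    }
    invisible(metadata)
}
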