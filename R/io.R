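#' Read an ASV count table from TSV
#'
#' Expects a tab-separated file with a header row of sample ids, ASV ids in
#' the first column, and an optional last column named `taxonomy` holding
#' semicolon-separated lineages. Counts must be non-negative integers;
#' offending cells are reported by ASV and sample. Row and column order are
#' preserved and no rows or columns are dropped.
#'
#' @param path path to a TSV file.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @return An [AsvTable].
#' @seealso [writeAsvTable()]
#' @export
readAsvTable <- function(path, kingdom = c("bacteria", "fungi")) {
    kingdom <- match.arg(kingdom)
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character")
    if (ncol(df) < 2L)
        stop("ASV table must have an id column and at least one sample")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate ASV ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    tax <- NULL
    if (tolower(names(df)[ncol(df)]) == "taxonomy") {
        tax <- setNames(df[[ncol(df)]], ids)
        df <- df[, -ncol(df), drop = FALSE]
    }
    samples <- names(df)[-1L]
    if (anyDuplicated(samples))
        stop("duplicate sample ids in ", path)
    m <- matrix(NA_real_, nrow(df), length(samples),
                dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
        v <- df[[j + 1L]]
        ok <- grepl("^[0-9]+$", v)
        if (!all(ok))
            stop(sprintf(
                "non-integer or negative count '%s' at ASV '%s', sample '%s'",
                v[!ok][1L], ids[!ok][1L], samples[j]))
        m[, j] <- as.numeric(v)
    }
    AsvTable(m, kingdom, taxonomy = tax)
}

#' Write an ASV count table to TSV
#'
#' @param x an [AsvTable].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAsvTable <- function(x, path) {
    stopifnot(is(x, "AsvTable"))
    df <- data.frame(asv_id = rownames(x),
                     counts(x), check.names = FALSE)
    tx <- taxonomy(x)
    if (!is.null(tx)) df$taxonomy <- unname(tx)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a soil function matrix from TSV
#'
#' Rows are samples (ids in the first column), columns are function names.
#' Missing cells and duplicate sample ids are errors; column names outside
#' the canonical twelve are accepted with a warning.
#'
#' @param path path to a TSV file.
#' @return A [FunctionMatrix].
#' @seealso [writeFunctionMatrix()]
#' @export
readFunctionMatrix <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate sample ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- ids
    if (anyNA(m)) {
        idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
        stop(sprintf("missing value for sample '%s', function '%s'",
                     rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
    }
    FunctionMatrix(m)
}

#' Write a soil function matrix to TSV
#'
#' Values are written with six significant digits.
#'
#' @param x a [FunctionMatrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFunctionMatrix <- function(x, path) {
    stopifnot(is(x, "FunctionMatrix"))
    df <- data.frame(sample_id = sampleIDs(x),
                     signif(fmValues(x), 6), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write sample metadata
#'
#' Tab-separated with columns `sample_id`, `treatment`, `replicate`.
#'
#' @param path TSV path.
#' @return `readSampleMetadata` returns a data.frame;
#'   `writeSampleMetadata` returns `path` invisibly.
#' @export
readSampleMetadata <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
    need <- c("sample_id", "treatment", "replicate")
    if (!all(need %in% names(df)))
        stop("metadata must have columns sample_id, treatment, replicate")
    df$sample_id <- as.character(df$sample_id)
    df$treatment <- as.character(df$treatment)
    df$replicate <- as.integer(df$replicate)
    df
}

#' @rdname readSampleMetadata
#' @param metadata data.frame as returned by [readSampleMetadata()].
#' @export
writeSampleMetadata <- function(metadata, path) {
    write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a co-occurrence network
#'
#' Writes either GraphML (node attribute `kingdom`; edge attributes `r`,
#' `p_adj`, `sign`; full double precision) for igraph/Gephi-style viewers,
#' or a `Source,Target,Weight,Sign` CSV edge list for spreadsheet import.
#' An empty network yields a valid file with headers (or no edge elements)
#' only.
#'
#' @param graph a [CoocGraph].
#' @param path output path.
#' @param format `"graphml"` or `"edge_csv"`.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(graph, path, format = c("graphml", "edge_csv")) {
    stopifnot(is(graph, "CoocGraph"))
    format <- match.arg(format)
    if (format == "graphml") {
        igraph::write_graph(graph@graph, path, format = "graphml")
    } else {
        ed <- graph@edges
        out <- data.frame(Source = ed$from, Target = ed$to,
                          Weight = ed$r, Sign = ed$sign)
        write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read a DAG specification for path modelling
#'
#' Reads a YAML file with a top-level `paths` sequence of `from: to`
#' two-element maps, or a simple `from -> to` line format, into the
#' two-column edge data.frame accepted by [fitPathModel()].
#'
#' @param path YAML file with a `paths:` list of `[from, to]` pairs, or a
#'   plain-text file of `from -> to` lines.
#' @return data.frame with columns `from` and `to`.
#' @export
readDag <- function(path) {
    txt <- readLines(path, warn = FALSE)
    if (any(grepl("^\\s*paths\\s*:", txt))) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("the yaml package is required to read YAML DAG files")
        spec <- yaml::read_yaml(path)
        pairs <- spec$paths
        edges <- do.call(rbind, lapply(pairs, function(p) {
            p <- unlist(p)
            if (length(p) != 2L) stop("each path must be a [from, to] pair")
            data.frame(from = p[[1L]], to = p[[2L]])
        }))
    } else {
        txt <- txt[grepl("->", txt, fixed = TRUE)]
        parts <- strsplit(txt, "->", fixed = TRUE)
        edges <- data.frame(
            from = trimws(vapply(parts, `[`, "", 1L)),
            to = trimws(vapply(parts, `[`, "", 2L)))
    }
    if (is.null(edges) || !nrow(edges)) stop("no paths found in ", path)
    edges
}
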