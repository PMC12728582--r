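#' Rarefy an ASV table to even depth
#'
#' Subsamples every sample's reads without replacement to exactly `depth`
#' (the common "level to the minimum sample depth" step). A single seeded
#' draw is used, not an average over draws.
#'
#' @param table an [AsvTable].
#' @param depth target reads per sample; defaults to the minimum sample
#'   total. Must be at least 1 and no larger than any sample's total.
#' @param seed optional integer seed.
#' @return A rarefied [AsvTable] (taxonomy and kingdom preserved).
#' @export
rarefyTable <- function(table, depth = NULL, seed = NULL) {
    stopifnot(is(table, "AsvTable"))
    m <- counts(table)
    tot <- colSums(m)
    if (is.null(depth)) depth <- min(tot)
    if (depth < 1L) stop("depth must be at least 1")
    low <- tot < depth
    if (any(low))
        stop("depth ", depth, " exceeds the total of sample(s): ",
             paste(colnames(m)[low], collapse = ", "))
    .check_seed(seed)
    # vegan heuristically warns when the smallest nonzero count exceeds 1;
    # depths are validated above, so muffle that specific warning
    r <- withCallingHandlers(
        t(vegan::rrarefy(t(m), depth)),
        warning = function(w) {
            if (grepl("observed counts", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    AsvTable(r, kingdom(table), taxonomy = taxonomy(table))
}

#' Observed ASV richness per sample
#'
#' @param table an [AsvTable].
#' @return Named integer vector: number of ASVs with nonzero count in each
#'   sample.
#' @export
sampleRichness <- function(table) {
    stopifnot(is(table, "AsvTable"))
    colSums(counts(table) > 0)
}

#' Faith's phylogenetic diversity per sample
#'
#' Rooted Faith's PD: for each sample, the sum of branch lengths of the
#' minimal subtree spanning the root and all ASVs present (count > 0).
#' Unrooted trees are midpoint-rooted with a message. Computed with
#' `picante::pd(..., include.root = TRUE)`.
#'
#' @param table an [AsvTable].
#' @param tree a `phylo` whose tips include every ASV present in any
#'   sample.
#' @return Named numeric vector of PD values per sample.
#' @export
faithPD <- function(table, tree) {
    stopifnot(is(table, "AsvTable"), inherits(tree, "phylo"))
    m <- counts(table)
    present <- rownames(m)[rowSums(m) > 0]
    missing <- setdiff(present, tree$tip.label)
    if (length(missing))
        stop("ASV(s) present but missing from the tree: ",
             paste(head(missing, 5), collapse = ", "))
    if (!ape::is.rooted(tree)) {
        message("midpoint-rooting unrooted tree for rooted PD")
        tree <- phangorn::midpoint(tree)
    }
    samp <- t(m)
    keep <- intersect(colnames(samp), tree$tip.label)
    samp <- samp[, keep, drop = FALSE]
    res <- picante::pd(samp, tree, include.root = TRUE)
    setNames(res$PD, rownames(res))
}

#' Combined microbial diversity index
#'
#' Min-max standardizes the bacterial and fungal richness vectors over
#' samples and averages the two standardized scores.
#'
#' @param bact_rich,fung_rich per-sample richness vectors over the same
#'   samples (named vectors are aligned by name).
#' @return Per-sample numeric vector in \[0, 1\].
#' @export
microbialDiversityIndex <- function(bact_rich, fung_rich) {
    if (length(bact_rich) != length(fung_rich))
        stop("richness vectors must cover the same samples")
    if (!is.null(names(bact_rich)) && !is.null(names(fung_rich))) {
        if (!setequal(names(bact_rich), names(fung_rich)))
            stop("richness vectors must cover the same samples")
        fung_rich <- fung_rich[names(bact_rich)]
    }
    (standardizeMinmax(bact_rich) + standardizeMinmax(fung_rich)) / 2
}

.genus_from_lineage <- function(lineage) {
    vapply(lineage, function(s) {
        if (is.na(s) || !nzchar(s)) return("unclassified_root")
        ranks <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
        ranks <- ranks[nzchar(ranks) & !grepl("^[a-z]__$", ranks)]
        if (length(ranks) >= 6L) return(ranks[6L])
        if (!length(ranks)) return("unclassified_root")
        paste0("unclassified_", ranks[length(ranks)])
    }, character(1L), USE.NAMES = FALSE)
}

#' Genus-level relative abundance
#'
#' Sums counts over ASVs sharing a genus (ASVs whose lineage stops short of
#' genus are pooled as `unclassified_<deepest rank>`) and divides by the
#' sample totals, so every column sums to 1.
#'
#' @param table an [AsvTable] with taxonomy.
#' @return genus x sample matrix of relative abundances.
#' @export
genusAbundance <- function(table) {
    stopifnot(is(table, "AsvTable"))
    tx <- taxonomy(table)
    if (is.null(tx)) stop("table has no taxonomy")
    m <- counts(table)
    tot <- colSums(m)
    if (any(tot == 0))
        stop("zero-total sample(s): ",
             paste(colnames(m)[tot == 0], collapse = ", "))
    genus <- .genus_from_lineage(tx)
    agg <- rowsum(m, group = genus)
    sweep(agg, 2L, tot, "/")
}
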