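#' Per-sample network complexity scores
#'
#' Builds the co-occurrence network(s), extracts every sample's subnetwork,
#' computes topology records, and ordinates them into one complexity score
#' per sample. The core-abundance filter is applied across all samples
#' jointly in both scopes. With `scope = "pooled"` one network is built
#' from all samples (one network per community type); with
#' `scope = "per_treatment"` a network is built from each treatment's
#' samples and each sample's subnetwork is taken from its own treatment's
#' network, all records being ordinated together.
#'
#' @param tables an [AsvTable] or list of tables (one per kingdom) sharing
#'   a sample set.
#' @param metadata data.frame with `sample_id` and `treatment` covering all
#'   samples.
#' @param params [coocParams()] settings.
#' @param scope `"pooled"` or `"per_treatment"`.
#' @return List with `scores` (named per-sample numeric), `complexity`
#'   (a [ComplexityResult]), `networks` (list of [CoocGraph]s), and
#'   `records` (topology data.frame).
#' @export
networkComplexityScores <- function(tables, metadata,
                                    params = coocParams(),
                                    scope = c("pooled", "per_treatment")) {
    scope <- match.arg(scope)
    if (is(tables, "AsvTable")) tables <- list(tables)
    core <- lapply(tables, filterCoreAsvs, params$min_mean_rel_abund)
    params0 <- params
    params0$min_mean_rel_abund <- 0   # already filtered jointly
    class(params0) <- "cooc_params"
    samp <- sampleIDs(core[[1L]])
    stopifnot(all(samp %in% metadata$sample_id))
    meta <- metadata[match(samp, metadata$sample_id), ]
    if (scope == "pooled") {
        nets <- list(all = buildNetwork(core, params0, graph_id = "all"))
        net_of <- setNames(rep("all", length(samp)), samp)
    } else {
        trts <- unique(meta$treatment)
        nets <- lapply(setNames(trts, trts), function(tr) {
            idx <- meta$sample_id[meta$treatment == tr]
            buildNetwork(lapply(core, function(tb) tb[, idx]),
                         params0, graph_id = as.character(tr))
        })
        net_of <- setNames(as.character(meta$treatment), samp)
    }
    records <- do.call(rbind, lapply(samp, function(s)
        topologyMetrics(sampleSubnetwork(nets[[net_of[[s]]]], core, s))))
    cx <- complexityIndex(records)
    list(scores = complexityScores(cx), complexity = cx,
         networks = nets, records = records)
}

#' One-way ANOVA with least-significant-difference letters
#'
#' Routine treatment comparison: one-way ANOVA followed by unadjusted
#' pairwise t-tests on the pooled residual variance (Fisher's LSD) at the
#' given significance level.
#'
#' @param values numeric response per sample.
#' @param groups treatment labels.
#' @param alpha significance level (default 0.05).
#' @return List with `anova_p`, `group_means`, and the matrix of pairwise
#'   LSD p-values.
#' @export
anovaLSD <- function(values, groups, alpha = 0.05) {
    groups <- as.factor(groups)
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1L]]
    pt_res <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                                     pool.sd = TRUE)
    list(anova_p = an[["Pr(>F)"]][1L],
         group_means = tapply(values, groups, mean),
         lsd_p = pt_res$p.value, alpha = alpha)
}

#' Run the full analysis pipeline on one dataset
#'
#' Convenience orchestration of every stage on a dataset shaped like the
#' output of [simulateDataset()]: rarefaction to the minimum depth per
#' kingdom, multifunctionality indices, richness and the combined
#' microbial diversity index, genus-level composition with Bray-Curtis
#' PERMANOVA per kingdom, bacterial / fungal / cross-kingdom networks with
#' per-sample subnetwork complexity, and the linking layer (AMI-complexity
#' regression, Mantel test of composition against function profiles, random
#' forest importance of microbial drivers, and a
#' diversity -> complexity -> multifunctionality path model).
#'
#' @param dataset list with `bacteria`, `fungi`, `functions`, `metadata`
#'   (see [simulateDataset()]).
#' @param params [coocParams()] used for all networks.
#' @param scope network scope passed to [networkComplexityScores()].
#' @param n_perm permutations for PERMANOVA and Mantel tests.
#' @param seed integer seed for rarefaction and permutation draws.
#' @return A list of per-stage results; see the individual functions.
#' @export
runPipeline <- function(dataset, params = coocParams(),
                        scope = c("pooled", "per_treatment"),
                        n_perm = 999L, seed = 1L) {
    scope <- match.arg(scope)
    meta <- validateMetadata(dataset$metadata, dataset$bacteria,
                             dataset$fungi, dataset$functions)
    bact <- rarefyTable(dataset$bacteria, seed = seed)
    fung <- rarefyTable(dataset$fungi, seed = seed + 1L)

    mfr <- multifunIndices(dataset$functions)

    rich_b <- sampleRichness(bact)
    rich_f <- sampleRichness(fung)
    mdi <- microbialDiversityIndex(rich_b, rich_f)

    gen_b <- genusAbundance(bact)
    gen_f <- genusAbundance(fung)
    d_gb <- brayCurtis(t(gen_b))
    d_gf <- brayCurtis(t(gen_f))
    grp <- meta$treatment[match(sampleIDs(bact), meta$sample_id)]
    perm_b <- permanovaTest(d_gb, grp, n_perm = n_perm, seed = seed + 2L)
    perm_f <- permanovaTest(d_gf, grp, n_perm = n_perm, seed = seed + 3L)
    comp_b <- pcoaOrdination(d_gb, k = 2L)
    comp_f <- pcoaOrdination(d_gf, k = 2L)

    nets <- list(
        bacteria = buildNetwork(bact, params, graph_id = "bacteria"),
        fungi = buildNetwork(fung, params, graph_id = "fungi"),
        microbial = buildNetwork(list(bact, fung), params,
                                 graph_id = "microbial"))
    cx <- networkComplexityScores(list(bact, fung), meta, params, scope)

    samp <- sampleIDs(dataset$functions)
    features <- data.frame(
        row.names = samp,
        diversity = mdi[samp],
        richness_bacteria = as.numeric(rich_b[samp]),
        richness_fungi = as.numeric(rich_f[samp]),
        composition_bacteria = comp_b$coords[samp, 1L],
        composition_fungi = comp_f$coords[samp, 1L],
        complexity = cx$scores[samp],
        AMI = ami(mfr)[samp],
        PMI.1 = pmi(mfr)[samp, "PMI.1"])

    reg <- olsFit(features$complexity, features$AMI)
    d_fun <- dist(stdFunctions(mfr))
    mant_b <- mantelTest(d_gb, d_fun, n_perm = n_perm, seed = seed + 4L)
    mant_f <- mantelTest(d_gf, d_fun, n_perm = n_perm, seed = seed + 5L)
    rf <- rfImportance(features[, c("diversity", "composition_bacteria",
                                    "composition_fungi", "complexity")],
                       features$AMI, seed = seed + 6L)
    dag <- data.frame(from = c("diversity", "complexity"),
                      to = c("complexity", "AMI"))
    sem <- fitPathModel(dag, features)

    list(multifun = mfr, richness = list(bacteria = rich_b,
                                         fungi = rich_f),
         diversity = mdi, metadata = meta,
         genus = list(bacteria = gen_b, fungi = gen_f),
         permanova = list(bacteria = perm_b, fungi = perm_f),
         networks = nets, complexity = cx, features = features,
         regression = reg,
         mantel = list(bacteria = mant_b, fungi = mant_f),
         rf_importance = rf, path_model = sem)
}
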