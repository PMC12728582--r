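#' Configuration for the synthetic study generator
#'
#' Bundles and validates the parameters of the generative model behind
#' [simulateDataset()]. The defaults emulate the field design the package
#' targets: three straw-returning treatments (no return CK, half-dose SBSH,
#' full-dose SBSF) with three replicate plots each, two kingdoms of ASVs,
#' treatment-dependent co-occurrence block structure, and twelve soil
#' functions driven by a latent connectivity signal. Block correlations
#' default to (CK 0.2, SBSH 0.8, SBSF 0.5), i.e. the half-dose treatment
#' carries the most tightly coupled guilds.
#'
#' @param n_treatments,n_replicates design size; both must be at least 2.
#'   Replicates are configurable upward for power analyses.
#' @param treatments treatment labels; defaults to CK/SBSH/SBSF when
#'   `n_treatments == 3`.
#' @param n_bacteria_asvs,n_fungi_asvs ASVs simulated per kingdom.
#' @param library_size named vector of reads per sample for `bacteria` and
#'   `fungi`. At desk scale the defaults keep reads-per-ASV comparable to a
#'   rarefied field dataset; a value below `10 * n_asvs` triggers a warning.
#' @param n_blocks number of co-occurring guild blocks; blocks are drawn
#'   from the most abundant ASVs of both kingdoms so that they survive the
#'   core-abundance filter, and each block mixes kingdoms.
#' @param block_fraction fraction of ASVs assigned to blocks.
#' @param block_rho_by_treatment per-treatment within-block latent
#'   correlation, each in `[0, 1)`; higher values make block co-occurrence
#'   easier to detect downstream.
#' @param complexity_effect coefficient linking the latent per-sample
#'   connectivity to every soil function (in units of that function's
#'   between-sample standard deviation).
#' @param noise_sd residual function noise, again relative to each
#'   function's standard deviation scale.
#' @param dispersion standard deviation of per-sample log-abundance
#'   deviations; larger values give stronger co-occurrence signal and more
#'   realistic zero-inflation.
#' @param base_sd standard deviation of baseline log mean abundances.
#' @param dirichlet_conc optional Dirichlet overdispersion concentration;
#'   `Inf` (default) keeps plain multinomial counts so expected relative
#'   abundances stay exact.
#' @param function_means,function_sds per-function location and scale used
#'   to place synthetic functions on unit-plausible scales (e.g. SOC around
#'   19.2 g/kg); cosmetic, not fitted.
#' @param seed integer seed; every random draw of the generator flows from
#'   it.
#'
#' @return A list of class `synth_config`.
#' @seealso [simulateDataset()]
#' @export
synthConfig <- function(n_treatments = 3L, n_replicates = 3L,
                        treatments = NULL,
                        n_bacteria_asvs = 120L, n_fungi_asvs = 60L,
                        library_size = c(bacteria = 1500L, fungi = 800L),
                        n_blocks = 6L, block_fraction = 0.6,
                        block_rho_by_treatment = NULL,
                        complexity_effect = 2, noise_sd = 0.2,
                        dispersion = 2.5, base_sd = 1.2,
                        dirichlet_conc = Inf,
                        function_means = NULL, function_sds = NULL,
                        seed = 1L) {
    if (n_treatments < 2L || n_replicates < 2L)
        stop("degenerate design: need >= 2 treatments and >= 2 replicates")
    if (is.null(treatments))
        treatments <- if (n_treatments == 3L) c("CK", "SBSH", "SBSF")
                      else paste0("T", seq_len(n_treatments))
    if (length(treatments) != n_treatments || anyDuplicated(treatments))
        stop("treatments must be ", n_treatments, " unique labels")
    if (is.null(block_rho_by_treatment))
        block_rho_by_treatment <-
            if (n_treatments == 3L) c(0.2, 0.8, 0.5)
            else seq(0.2, 0.8, length.out = n_treatments)
    if (length(block_rho_by_treatment) != n_treatments)
        stop("block_rho_by_treatment must have one value per treatment")
    if (any(block_rho_by_treatment < 0 | block_rho_by_treatment >= 1))
        stop("block_rho values must lie in [0, 1)")
    if (any(c(n_bacteria_asvs, n_fungi_asvs, n_blocks) < 1L))
        stop("counts of ASVs and blocks must be positive")
    if (!all(c("bacteria", "fungi") %in% names(library_size)))
        stop("library_size must be named with 'bacteria' and 'fungi'")
    if (library_size[["bacteria"]] < 10 * n_bacteria_asvs ||
        library_size[["fungi"]] < 10 * n_fungi_asvs)
        warning("library_size below 10 x n_asvs; counts will be very sparse",
                call. = FALSE)
    if (noise_sd < 0 || dispersion <= 0 || base_sd < 0)
        stop("noise_sd, dispersion and base_sd must be positive")
    if (is.null(function_means))
        function_means <- c(ALP = 45, AP = 7.9, TP = 1.04, MBP = 15,
                            AN = 8, NN = 12, MBN = 45, TN = 1.4,
                            Ure = 30, MBC = 250, SOC = 19.2, SSC = 20)
    if (is.null(function_sds))
        function_sds <- 0.15 * function_means
    stopifnot(length(function_sds) == length(function_means))
    structure(list(
        n_treatments = as.integer(n_treatments),
        n_replicates = as.integer(n_replicates),
        treatments = treatments,
        n_bacteria_asvs = as.integer(n_bacteria_asvs),
        n_fungi_asvs = as.integer(n_fungi_asvs),
        library_size = library_size,
        n_blocks = as.integer(n_blocks),
        block_fraction = block_fraction,
        block_rho_by_treatment =
            setNames(block_rho_by_treatment, treatments),
        complexity_effect = complexity_effect,
        noise_sd = noise_sd,
        dispersion = dispersion,
        base_sd = base_sd,
        dirichlet_conc = dirichlet_conc,
        function_means = function_means,
        function_sds = function_sds,
        seed = as.integer(seed)), class = "synth_config")
}

# block assignment: round-robin over the most abundant ASVs of both
# kingdoms so each block mixes kingdoms and survives the core filter
.assign_blocks <- function(log_mu_b, log_mu_f, n_blocks, block_fraction) {
    nb <- length(log_mu_b); nf <- length(log_mu_f)
    kb <- max(n_blocks, ceiling(block_fraction * nb))
    kf <- max(n_blocks, ceiling(block_fraction * nf))
    pool_b <- order(log_mu_b, decreasing = TRUE)[seq_len(min(kb, nb))]
    pool_f <- order(log_mu_f, decreasing = TRUE)[seq_len(min(kf, nf))] + nb
    # interleave the two kingdoms before dealing out the blocks
    pool <- integer(0)
    i <- 1L
    while (i <= max(length(pool_b), length(pool_f))) {
        if (i <= length(pool_b)) pool <- c(pool, pool_b[i])
        if (i <= length(pool_f)) pool <- c(pool, pool_f[i])
        i <- i + 1L
    }
    blocks <- integer(nb + nf)
    blocks[pool] <- rep_len(seq_len(n_blocks), length(pool))
    blocks
}

.make_lineage <- function(kingdom, block, idx, truncated) {
    dom <- if (kingdom == "bacteria") "d__Bacteria" else "d__Fungi"
    stem <- sprintf("%s;p__Phylum%02d;c__Class%02d;o__Order%02d;f__Family%02d",
                    dom, idx %% 5L + 1L, idx %% 7L + 1L, idx %% 11L + 1L,
                    idx %% 13L + 1L)
    if (truncated) return(stem)
    genus <- if (block > 0L) sprintf("g__Guild%02d", block)
             else sprintf("g__Taxon%03d", idx %% 37L + 1L)
    paste(stem, genus, sep = ";")
}

#' Simulate a synthetic straw-returning study
#'
#' Fully seeded generative model: (1) baseline log-normal mean abundances
#' per ASV; (2) per-sample log-abundance deviations from a multivariate
#' normal whose correlation is block-diagonal, with within-block correlation
#' given by the sample's treatment; (3) counts drawn multinomially at the
#' kingdom's library size from the softmax of log-abundances; (4) a latent
#' sample connectivity equal to the treatment's block correlation plus
#' N(0, 0.02) jitter; (5) each soil function equal to its baseline plus
#' `complexity_effect` times connectivity (on the function's scale) plus
#' Gaussian noise.
#'
#' @param config a [synthConfig()] object.
#' @return A list with elements `bacteria` and `fungi` ([AsvTable]s with
#'   synthetic taxonomy), `functions` (a [FunctionMatrix]), `metadata`
#'   (data.frame: sample_id, treatment, replicate), and `ground_truth`
#'   (list: per-sample `connectivity`, per-ASV `blocks`, `beta_c`,
#'   `block_rho`).
#' @examples
#' ds <- simulateDataset(synthConfig(seed = 7))
#' ds$bacteria
#' head(ds$ground_truth$connectivity)
#' @export
simulateDataset <- function(config = synthConfig()) {
    stopifnot(inherits(config, "synth_config"))
    set.seed(config$seed)
    nb <- config$n_bacteria_asvs
    nf <- config$n_fungi_asvs
    asv_b <- sprintf("bASV_%03d", seq_len(nb))
    asv_f <- sprintf("fASV_%03d", seq_len(nf))
    meta <- data.frame(
        sample_id = paste(rep(config$treatments, each = config$n_replicates),
                          seq_len(config$n_replicates), sep = "_"),
        treatment = rep(config$treatments, each = config$n_replicates),
        replicate = rep(seq_len(config$n_replicates), config$n_treatments),
        stringsAsFactors = FALSE)
    ns <- nrow(meta)

    log_mu_b <- rnorm(nb, 0, config$base_sd)
    log_mu_f <- rnorm(nf, 0, config$base_sd)
    blocks <- .assign_blocks(log_mu_b, log_mu_f, config$n_blocks,
                             config$block_fraction)
    names(blocks) <- c(asv_b, asv_f)

    n_asv <- nb + nf
    cnt_b <- matrix(0, nb, ns, dimnames = list(asv_b, meta$sample_id))
    cnt_f <- matrix(0, nf, ns, dimnames = list(asv_f, meta$sample_id))
    connectivity <- numeric(ns)
    for (s in seq_len(ns)) {
        rho <- config$block_rho_by_treatment[[meta$treatment[s]]]
        shared <- rnorm(config$n_blocks)
        eps <- rnorm(n_asv)
        z <- eps
        blocked <- blocks > 0L
        z[blocked] <- sqrt(rho) * shared[blocks[blocked]] +
            sqrt(1 - rho) * eps[blocked]
        la_b <- log_mu_b + config$dispersion * z[seq_len(nb)]
        la_f <- log_mu_f + config$dispersion * z[nb + seq_len(nf)]
        p_b <- exp(la_b - max(la_b)); p_b <- p_b / sum(p_b)
        p_f <- exp(la_f - max(la_f)); p_f <- p_f / sum(p_f)
        if (is.finite(config$dirichlet_conc)) {
            p_b <- rgamma(nb, shape = p_b * config$dirichlet_conc)
            p_b <- p_b / sum(p_b)
            p_f <- rgamma(nf, shape = p_f * config$dirichlet_conc)
            p_f <- p_f / sum(p_f)
        }
        cnt_b[, s] <- rmultinom(1L, config$library_size[["bacteria"]], p_b)
        cnt_f[, s] <- rmultinom(1L, config$library_size[["fungi"]], p_f)
        connectivity[s] <- rho + rnorm(1L, 0, 0.02)
    }
    names(connectivity) <- meta$sample_id

    mu <- config$function_means
    sdv <- config$function_sds
    fn <- matrix(0, ns, length(mu),
                 dimnames = list(meta$sample_id, names(mu)))
    for (j in seq_along(mu))
        fn[, j] <- mu[j] + config$complexity_effect * connectivity * sdv[j] +
            rnorm(ns, 0, config$noise_sd * sdv[j])

    truncated <- runif(n_asv) < 0.1
    tax <- vapply(seq_len(n_asv), function(i) {
        kd <- if (i <= nb) "bacteria" else "fungi"
        .make_lineage(kd, blocks[i], i, truncated[i])
    }, character(1L))
    names(tax) <- names(blocks)

    list(bacteria = AsvTable(cnt_b, "bacteria",
                             taxonomy = tax[asv_b]),
         fungi = AsvTable(cnt_f, "fungi", taxonomy = tax[asv_f]),
         functions = FunctionMatrix(fn),
         metadata = meta,
         ground_truth = list(connectivity = connectivity, blocks = blocks,
                             beta_c = config$complexity_effect,
                             block_rho = config$block_rho_by_treatment))
}

#' @importFrom stats rmultinom rgamma
NULL

#' Simulate a random phylogeny over a set of ASVs
#'
#' Coalescent-style rooted bifurcating tree with strictly positive branch
#' lengths and tips exactly equal to `asv_ids`, for exercising
#' phylogenetic-diversity computations.
#'
#' @param asv_ids unique tip labels (at least 2).
#' @param seed optional integer seed.
#' @return An [ape][ape::read.tree] `phylo` object.
#' @export
simulateTree <- function(asv_ids, seed = NULL) {
    if (length(asv_ids) < 2L)
        stop("need at least 2 tips")
    if (anyDuplicated(asv_ids))
        stop("duplicate tip ids: ",
             paste(unique(asv_ids[duplicated(asv_ids)]), collapse = ", "))
    .check_seed(seed)
    ape::rcoal(length(asv_ids), tip.label = asv_ids)
}
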