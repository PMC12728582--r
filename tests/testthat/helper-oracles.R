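# Independent brute-force oracles used to check the package's
# implementations. These deliberately avoid the code paths under test.

# Benjamini-Hochberg step-up, written directly from the definition
bh_stepup <- function(p) {
    m <- length(p)
    o <- order(p)
    sorted <- p[o]
    q <- numeric(m)
    running <- Inf
    for (i in rev(seq_len(m))) {
        running <- min(running, sorted[i] * m / i)
        q[i] <- min(running, 1)
    }
    out <- numeric(m)
    out[o] <- q
    out
}

# two-sided t-approximation p for a correlation (independent arithmetic)
t_approx_p <- function(r, n) {
    if (abs(r) >= 1) return(.Machine$double.xmin)
    tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
    max(2 * stats::pt(tt, n - 2, lower.tail = FALSE), .Machine$double.xmin)
}

# all-pairs Spearman network by brute force
brute_network <- function(m, r_threshold, p_threshold, adjust = "BH",
                          positive_only = FALSE) {
    ids <- rownames(m)
    n <- ncol(m)
    pairs <- t(combn(length(ids), 2))
    r <- p <- numeric(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
        r[k] <- stats::cor(m[pairs[k, 1], ], m[pairs[k, 2], ],
                           method = "spearman")
        p[k] <- t_approx_p(r[k], n)
    }
    q <- if (adjust == "BH") bh_stepup(p) else p
    keep <- abs(r) > r_threshold & q < p_threshold
    if (positive_only) keep <- keep & r > 0
    data.frame(from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]],
               r = r[keep], p_adj = q[keep])
}

# Floyd-Warshall distances and shortest-path counts from an adjacency matrix
floyd_paths <- function(adj) {
    n <- nrow(adj)
    d <- matrix(Inf, n, n)
    sigma <- matrix(0, n, n)
    d[adj > 0] <- 1
    sigma[adj > 0] <- 1
    diag(d) <- 0
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j || i == k || j == k) next
        alt <- d[i, k] + d[k, j]
        if (alt < d[i, j]) {
            d[i, j] <- alt
            sigma[i, j] <- sigma[i, k] * sigma[k, j]
        } else if (is.finite(alt) && alt == d[i, j]) {
            sigma[i, j] <- sigma[i, j] + sigma[i, k] * sigma[k, j]
        }
    }
    list(d = d, sigma = sigma)
}

# the seven topology metrics by brute force
brute_topology <- function(adj) {
    n <- nrow(adj)
    e <- sum(adj) / 2
    deg <- rowSums(adj)
    cc <- mean(vapply(seq_len(n), function(v) {
        if (deg[v] < 2) return(0)
        nb <- which(adj[v, ] > 0)
        sum(adj[nb, nb]) / 2 / choose(deg[v], 2)
    }, 1))
    fp <- floyd_paths(adj)
    ut <- upper.tri(fp$d)
    finite <- is.finite(fp$d) & ut
    apl <- if (any(finite)) mean(fp$d[finite]) else 0
    btw <- vapply(seq_len(n), function(v) {
        s <- 0
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (i >= j || i == v || j == v) next
            if (is.finite(fp$d[i, j]) &&
                fp$d[i, v] + fp$d[v, j] == fp$d[i, j])
                s <- s + fp$sigma[i, v] * fp$sigma[v, j] / fp$sigma[i, j]
        }
        s
    }, 1)
    btw_norm <- if (n >= 3) btw / ((n - 1) * (n - 2) / 2) else rep(0, n)
    list(n_nodes = n, n_edges = e, avg_degree = 2 * e / n,
         clustering_coef = cc, avg_path_length = apl,
         density = if (n >= 2) 2 * e / (n * (n - 1)) else 0,
         mean_betweenness = mean(btw_norm))
}

# rooted Faith's PD by brute force: union of root-path edges of present tips
brute_faith_pd <- function(tree, tips) {
    if (!length(tips)) return(0)
    root <- ape::Ntip(tree) + 1L
    edges <- integer(0)
    for (tip in tips) {
        node <- which(tree$tip.label == tip)
        while (node != root) {
            e <- which(tree$edge[, 2] == node)
            edges <- c(edges, e)
            node <- tree$edge[e, 1]
        }
    }
    sum(tree$edge.length[unique(edges)])
}

# DAG total effects via the matrix geometric series (I - B)^-1 - I
brute_total_effects <- function(pm) {
    vars <- unique(c(pm@edges$from, pm@edges$to))
    B <- matrix(0, length(vars), length(vars),
                dimnames = list(vars, vars))
    co <- pathCoefficients(pm)
    for (i in seq_len(nrow(co)))
        B[co$predictor[i], co$response[i]] <- co$estimate[i]
    solve(diag(length(vars)) - B) - diag(length(vars))
}

# small random count table with an optional correlated pair block
rand_table <- function(n_asv, n_samp, seed, kingdom = "bacteria",
                       corr_pairs = 0, lib = 200 * n_asv) {
    set.seed(seed)
    base <- stats::rnorm(n_asv, 0, 1)
    m <- matrix(0, n_asv, n_samp,
                dimnames = list(sprintf("%s_%02d", substr(kingdom, 1, 1),
                                        seq_len(n_asv)),
                                sprintf("s%02d", seq_len(n_samp))))
    for (s in seq_len(n_samp)) {
        z <- stats::rnorm(n_asv)
        if (corr_pairs > 0) {
            shared <- stats::rnorm(corr_pairs)
            for (b in seq_len(corr_pairs)) {
                idx <- c(2 * b - 1, 2 * b)
                z[idx] <- sqrt(0.9) * shared[b] + sqrt(0.1) * z[idx]
            }
        }
        p <- exp(base + 2 * z)
        m[, s] <- stats::rmultinom(1, lib, p / sum(p))
    }
    AsvTable(m, kingdom)
}

# desk-scale network settings used by the synthetic recovery analyses
desk_params <- function() {
    coocParams(r_threshold = 0.6, p_threshold = 0.05, adjust = "none")
}

# one desk-scale synthetic recovery run: per-treatment networks at the
# calibrated thresholds, per-sample subnetwork complexity scores
desk_recovery_run <- function(seed, beta = 2, noise = 0.2,
                              rho = c(0.2, 0.5, 0.8)) {
    cfg <- synthConfig(n_replicates = 10, block_rho_by_treatment = rho,
                       complexity_effect = beta, noise_sd = noise,
                       seed = seed)
    ds <- simulateDataset(cfg)
    bact <- rarefyTable(ds$bacteria, seed = seed)
    fung <- rarefyTable(ds$fungi, seed = seed + 1)
    res <- networkComplexityScores(list(bact, fung), ds$metadata,
                                   desk_params(), scope = "per_treatment")
    tr <- ds$metadata$treatment[match(names(res$scores),
                                      ds$metadata$sample_id)]
    list(scores = res$scores,
         rho = unname(cfg$block_rho_by_treatment[tr]),
         ami = ami(computeAMI(ds$functions))[names(res$scores)])
}
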