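test_that("the core-abundance filter keeps exactly the abundant ASVs", {
    # one ASV pinned at 0.6%, one at 0.4%, in every sample
    m <- matrix(0, 3, 6, dimnames = list(c("hi", "lo", "rest"),
                                         paste0("s", 1:6)))
    m["hi", ] <- 6; m["lo", ] <- 4; m["rest", ] <- 990
    tb <- AsvTable(m, "bacteria")
    kept <- rownames(filterCoreAsvs(tb))
    expect_true("hi" %in% kept)
    expect_false("lo" %in% kept)

    solo <- AsvTable(matrix(5, 1, 5, dimnames = list("only",
                                                     paste0("s", 1:5))),
                     "fungi")
    expect_identical(rownames(filterCoreAsvs(solo)), "only")

    tb2 <- rand_table(300, 8, seed = 2, lib = 5000)
    rel <- sweep(counts(tb2), 2, colSums(counts(tb2)), "/")
    expect_identical(rownames(filterCoreAsvs(tb2)),
                     rownames(tb2)[rowMeans(rel) > 0.005])
})

test_that("the Spearman edge test matches the rank formula", {
    expect_equal(spearmanEdgeTest(1:8, (1:8)^2)$r, 1)
    expect_equal(spearmanEdgeTest(1:8, rev(1:8))$r, -1)
    res <- spearmanEdgeTest(1:5, c(2, 1, 4, 3, 5))
    expect_equal(res$r, 0.8)   # 1 - 6*4/(5*24)
    expect_equal(res$p_raw, t_approx_p(0.8, 5), tolerance = 1e-12)
    expect_error(spearmanEdgeTest(rep(1, 6), 1:6),
                 class = "rhizofun_constant_vector")
    expect_error(spearmanEdgeTest(1:4, 4:1), "at least 5")
})

test_that("BH adjustment reproduces the step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.2), 0.2)
    set.seed(77)
    for (i in 1:5) {
        p <- runif(1000)
        expect_equal(bhAdjust(p), bh_stepup(p), tolerance = 1e-14)
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("perfectly co-ranked ASVs form one positive edge", {
    m <- rbind(a = 1:10, b = (1:10) * 3 + 2,
               c = c(5, 3, 8, 1, 9, 2, 7, 4, 10, 6))
    colnames(m) <- paste0("s", 1:10)
    net <- buildNetwork(AsvTable(m, "bacteria"),
                        coocParams(min_mean_rel_abund = 0))
    ed <- networkEdges(net)
    expect_equal(nrow(ed), 1L)
    expect_setequal(c(ed$from, ed$to), c("a", "b"))
    expect_identical(ed$sign, "+")
    expect_equal(ed$r, 1)
})

test_that("network defaults mirror the study conventions", {
    p <- coocParams()
    expect_equal(p$r_threshold, 0.70)
    expect_equal(p$p_threshold, 0.01)
    expect_equal(p$min_mean_rel_abund, 0.005)
    expect_identical(p$adjust, "BH")
    expect_false(p$positive_only)
})

test_that("edge sets equal the brute-force all-pairs oracle", {
    for (seed in c(3, 14, 25)) {
        tb <- rand_table(8, 12, seed = seed, corr_pairs = 3)
        params <- coocParams(min_mean_rel_abund = 0, r_threshold = 0.4,
                             p_threshold = 0.2)
        net <- buildNetwork(tb, params)
        oracle <- brute_network(counts(tb), 0.4, 0.2)
        ed <- networkEdges(net)
        key <- function(a, b) paste(pmin(a, b), pmax(a, b))
        expect_setequal(key(ed$from, ed$to), key(oracle$from, oracle$to))
        ord <- match(key(ed$from, ed$to), key(oracle$from, oracle$to))
        expect_equal(ed$r, oracle$r[ord], tolerance = 1e-12)
        expect_equal(ed$p_adj, oracle$p_adj[ord], tolerance = 1e-12)
    }
    expect_error(buildNetwork(rand_table(5, 4, seed = 1),
                              coocParams(min_mean_rel_abund = 0)),
                 "at least 5 samples")
})

test_that("canonical graphs yield their closed-form topology", {
    k4 <- topologyMetrics(igraph::make_full_graph(4))
    expect_equal(k4$n_nodes, 4L)
    expect_equal(k4$n_edges, 6L)
    expect_equal(k4$avg_degree, 3)
    expect_equal(k4$density, 1)
    expect_equal(k4$clustering_coef, 1)
    expect_equal(k4$avg_path_length, 1)
    expect_equal(k4$mean_betweenness, 0)

    p4 <- topologyMetrics(igraph::make_ring(4, circular = FALSE))
    expect_equal(p4$avg_degree, 1.5)
    expect_equal(p4$density, 0.5)
    expect_equal(p4$clustering_coef, 0)
    expect_equal(p4$avg_path_length, 10 / 6)

    star <- igraph::make_star(4, mode = "undirected", center = 1)
    btw <- igraph::betweenness(star, normalized = TRUE)
    expect_equal(unname(btw[1]), 1)
    expect_equal(unname(btw[2]), 0)
    st <- topologyMetrics(star)
    expect_equal(st$mean_betweenness, 0.25)

    empty <- topologyMetrics(igraph::make_empty_graph(0, directed = FALSE))
    expect_true(empty$is_empty)
    expect_equal(empty$n_nodes + empty$n_edges + empty$avg_degree, 0)
})

test_that("topology of arbitrary graphs matches the brute-force oracle", {
    set.seed(55)
    for (i in 1:10) {
        n <- sample(4:10, 1)
        adj <- matrix(0, n, n)
        adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.35)
        adj <- adj + t(adj)
        g <- igraph::graph_from_adjacency_matrix(adj, "undirected")
        got <- topologyMetrics(g)
        want <- brute_topology(adj)
        for (metric in names(want))
            expect_equal(got[[metric]], want[[metric]], tolerance = 1e-10,
                         label = paste("metric", metric, "rep", i))
    }
})

test_that("subnetworks are induced subgraphs on present ASVs", {
    tb <- rand_table(10, 12, seed = 9, corr_pairs = 4)
    net <- buildNetwork(tb, coocParams(min_mean_rel_abund = 0,
                                       r_threshold = 0.3,
                                       p_threshold = 0.5, adjust = "none"))
    expect_gt(igraph::ecount(networkGraph(net)), 2)
    cnt <- counts(tb)

    # a sample containing every node reproduces the network
    full <- cnt[, 1, drop = FALSE]; full[full == 0] <- 1
    tb_full <- AsvTable(cbind(cnt, sAll = full[, 1]), "bacteria")
    sub_all <- sampleSubnetwork(net, tb_full, "sAll")
    expect_equal(igraph::ecount(networkGraph(sub_all)),
                 igraph::ecount(networkGraph(net)))

    # a sample containing no nodes gives the empty subnetwork
    tb_none <- AsvTable(cbind(cnt, sNone = 0L), "bacteria")
    sub_none <- sampleSubnetwork(net, tb_none, "sNone")
    expect_equal(igraph::vcount(networkGraph(sub_none)), 0)

    # induced-subgraph oracle on every real sample
    nodes <- igraph::V(networkGraph(net))$name
    ed <- networkEdges(net)
    for (s in sampleIDs(tb)) {
        sub <- sampleSubnetwork(net, tb, s)
        present <- nodes[cnt[nodes, s] > 0]
        expect_setequal(igraph::V(networkGraph(sub))$name, present)
        want <- ed[ed$from %in% present & ed$to %in% present, ]
        expect_equal(nrow(networkEdges(sub)), nrow(want))
    }
    expect_error(sampleSubnetwork(net, tb, "nope"), "unknown sample")

    # monotonicity: adding a present ASV never shrinks the subnetwork
    s <- sampleIDs(tb)[3]
    base <- sampleSubnetwork(net, tb, s)
    absent <- setdiff(nodes, nodes[cnt[nodes, s] > 0])
    if (length(absent)) {
        cnt2 <- cnt; cnt2[absent[1], s] <- 1
        grown <- sampleSubnetwork(net, AsvTable(cnt2, "bacteria"), s)
        expect_gte(igraph::vcount(networkGraph(grown)),
                   igraph::vcount(networkGraph(base)))
        expect_gte(igraph::ecount(networkGraph(grown)),
                   igraph::ecount(networkGraph(base)))
    }
})

test_that("cross-kingdom networks test cross-kingdom pairs symmetrically", {
    b <- rand_table(6, 10, seed = 41, kingdom = "bacteria", corr_pairs = 2)
    f <- rand_table(6, 10, seed = 42, kingdom = "fungi", corr_pairs = 2)
    params <- coocParams(min_mean_rel_abund = 0, r_threshold = 0.3,
                         p_threshold = 0.4)
    n1 <- buildNetwork(list(b, f), params)
    n2 <- buildNetwork(list(f, b), params)
    key <- function(ed) sort(paste(pmin(ed$from, ed$to),
                                   pmax(ed$from, ed$to)))
    expect_identical(key(networkEdges(n1)), key(networkEdges(n2)))
    expect_false(igraph::any_loop(networkGraph(n1)))
    kd <- igraph::vertex_attr(networkGraph(n1), "kingdom")
    expect_true(all(kd %in% c("bacteria", "fungi")))

    oracle <- brute_network(rbind(counts(b), counts(f)), 0.3, 0.4)
    expect_equal(nrow(networkEdges(n1)), nrow(oracle))
})

test_that("complexity scores follow the dominant topology gradient", {
    rec <- do.call(rbind, lapply(1:6, function(i) {
        r <- topologyMetrics(igraph::make_full_graph(4), graph_id = i)
        r$avg_degree <- i          # single varying metric
        r
    }))
    expect_warning(cx <- complexityIndex(rec), "constant")
    sc <- complexityScores(cx)
    expect_true(all(diff(sc) > 0))
    expect_lt(abs(mean(sc)), 1e-10)

    # identical records receive identical scores
    rec2 <- rec
    rec2$avg_degree[6] <- rec2$avg_degree[5]
    expect_warning(cx2 <- complexityIndex(rec2), "constant")
    sc2 <- complexityScores(cx2)
    expect_equal(unname(sc2[5]), unname(sc2[6]), tolerance = 1e-12)

    expect_error(complexityIndex(rec[1:2, ]), "at least 3")
})
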