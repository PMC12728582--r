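test_that("rarefaction hits the target depth exactly and is seeded", {
    tb <- rand_table(30, 6, seed = 11)
    r1 <- rarefyTable(tb, depth = 100, seed = 9)
    r2 <- rarefyTable(tb, depth = 100, seed = 9)
    expect_identical(counts(r1), counts(r2))
    expect_true(all(colSums(counts(r1)) == 100))
    expect_true(all(counts(r1) <= counts(tb)))

    # depth equal to every total leaves the table unchanged
    same <- rarefyTable(tb, depth = min(colSums(counts(tb))), seed = 1)
    expect_true(all(colSums(counts(same)) == min(colSums(counts(tb)))))
    full <- rarefyTable(tb, depth = unique(colSums(counts(tb)))[1], seed = 1)
    expect_identical(counts(full), counts(tb))

    m <- counts(tb); m[, 2] <- 0; m[1, 2] <- 5
    expect_error(rarefyTable(AsvTable(m, "bacteria"), depth = 100),
                 colnames(m)[2])
})

test_that("rarefied counts match the hypergeometric expectation", {
    m <- matrix(c(40, 25, 20, 10, 5, 60, 20, 10, 6, 4), 5, 2,
                dimnames = list(paste0("a", 1:5), c("s1", "s2")))
    tb <- AsvTable(m, "bacteria")
    depth <- 50
    acc <- matrix(0, 5, 2)
    n_draw <- 1000
    for (i in seq_len(n_draw))
        acc <- acc + counts(rarefyTable(tb, depth, seed = i))
    avg <- acc / n_draw
    expected <- sweep(m, 2, colSums(m), "/") * depth
    # hypergeometric variance, then 3 standard errors of the mean
    N <- matrix(rep(colSums(m), each = 5), 5)
    vr <- depth * (m / N) * (1 - m / N) * (N - depth) / (N - 1)
    expect_true(all(abs(avg - expected) <= 3 * sqrt(vr / n_draw) + 1e-9))
})

test_that("richness counts nonzero ASVs per sample", {
    m <- matrix(c(3, 0, 0, 5, 1, 1), 3, 2, byrow = TRUE,
                dimnames = list(paste0("a", 1:3), c("s1", "s2")))
    expect_equal(unname(sampleRichness(AsvTable(m, "bacteria"))), c(2, 2))
    m[, 1] <- 0
    expect_equal(unname(sampleRichness(AsvTable(m, "fungi"))), c(0, 2))

    tb <- rand_table(200, 8, seed = 5, lib = 2000)
    expect_equal(sampleRichness(tb), colSums(counts(tb) > 0))
})

test_that("Faith's PD equals the brute-force union of root paths", {
    ids <- sprintf("t%02d", 1:10)
    tree <- simulateTree(ids, seed = 6)
    set.seed(31)
    m <- matrix(rbinom(10 * 6, 1, 0.5) * rpois(10 * 6, 4), 10, 6,
                dimnames = list(ids, paste0("s", 1:6)))
    m[, 1] <- 5                       # all tips present
    m[, 2] <- c(3, rep(0, 9))         # single tip
    tb <- AsvTable(m, "fungi")
    pd <- faithPD(tb, tree)
    expect_equal(unname(pd["s1"]), sum(tree$edge.length), tolerance = 1e-10)
    oracle <- vapply(colnames(m), function(s)
        brute_faith_pd(tree, rownames(m)[m[, s] > 0]), 1)
    expect_equal(pd, oracle, tolerance = 1e-10)

    # monotone as tips are added
    grow <- m[, 3, drop = FALSE]
    present <- which(grow[, 1] > 0)
    absent <- setdiff(seq_along(ids), present)
    last <- unname(pd["s3"])
    for (add in absent) {
        grow[add, 1] <- 1
        val <- unname(faithPD(AsvTable(grow, "fungi"), tree))
        expect_gte(val, last - 1e-12)
        last <- val
    }

    bad <- AsvTable(matrix(1, 2, 2, dimnames = list(c("t01", "zzz"),
                                                    c("s1", "s2"))),
                    "fungi")
    expect_error(faithPD(bad, tree), "zzz")
})

test_that("the microbial diversity index averages standardized richness", {
    expect_equal(unname(microbialDiversityIndex(c(10, 20, 30), c(5, 10, 15))),
                 c(0, 0.5, 1))
    b <- c(s1 = 12, s2 = 30, s3 = 21)
    expect_equal(microbialDiversityIndex(b, b), standardizeMinmax(b))
    # the sample attaining both maxima scores 1
    f <- c(s1 = 4, s2 = 9, s3 = 6)
    expect_equal(unname(microbialDiversityIndex(b, f)["s2"]), 1)
    expect_error(microbialDiversityIndex(c(1, 1, 1), c(1, 2, 3)),
                 class = "rhizofun_degenerate_range")
})

test_that("genus abundances aggregate lineages and sum to one", {
    m <- matrix(c(3, 2, 1, 2, 4, 1, 1, 2), 4, 2,
                dimnames = list(paste0("a", 1:4), c("s1", "s2")))
    tx <- c(a1 = "d__B;p__P;c__C;o__O;f__F;g__Genus1",
            a2 = "d__B;p__P;c__C;o__O;f__F;g__Genus1",
            a3 = "d__B;p__P;c__C;o__O;f__F;g__Genus2",
            a4 = "d__B;p__P;c__C;o__O;f__F2")      # truncated at family
    tb <- AsvTable(m, "bacteria", taxonomy = tx)
    g <- genusAbundance(tb)
    expect_equal(g["g__Genus1", "s1"], 5 / 8)
    expect_equal(g["unclassified_f__F2", "s1"], 2 / 8)
    expect_equal(unname(colSums(g)), c(1, 1), tolerance = 1e-12)

    # brute-force group-and-sum on a seeded synthetic table
    ds <- simulateDataset(synthConfig(seed = 13))
    gb <- genusAbundance(ds$bacteria)
    cnt <- counts(ds$bacteria)
    lineages <- taxonomy(ds$bacteria)
    for (pick in c(1, 7, 20)) {
        gname <- rownames(gb)[pick]
        idx <- vapply(lineages, function(s) {
            parts <- strsplit(s, ";")[[1]]
            if (length(parts) >= 6) parts[6] == gname
            else paste0("unclassified_", parts[length(parts)]) == gname
        }, TRUE)
        expect_equal(gb[gname, ],
                     colSums(cnt[idx, , drop = FALSE]) / colSums(cnt),
                     tolerance = 1e-12)
    }
})

test_that("Bray-Curtis honors its boundary cases", {
    m <- rbind(a = c(3, 0, 1), b = c(3, 0, 1), c = c(0, 5, 0))
    d <- as.matrix(brayCurtis(m))
    expect_equal(d["a", "b"], 0)
    expect_equal(d["a", "c"], 1)   # disjoint support
    expect_true(all(diag(d) == 0))
})
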