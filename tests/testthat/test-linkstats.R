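test_that("correlation matrices match the textbook formulas", {
    set.seed(12)
    m <- matrix(rnorm(9 * 5), 9, dimnames = list(NULL, letters[1:5]))
    res <- correlationMatrix(m)
    expect_equal(res$r["a", "a"], 1)
    for (pair in list(c("a", "b"), c("c", "e"))) {
        x <- m[, pair[1]]; y <- m[, pair[2]]
        r <- sum((x - mean(x)) * (y - mean(y))) /
            sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
        expect_equal(res$r[pair[1], pair[2]], r, tolerance = 1e-12)
        expect_equal(res$p[pair[1], pair[2]], t_approx_p(r, 9),
                     tolerance = 1e-12)
    }
    m2 <- cbind(m, neg = -m[, "a"])
    expect_equal(correlationMatrix(m2)$r["a", "neg"], -1)

    sp <- correlationMatrix(m, method = "spearman")
    expect_equal(sp$r["a", "b"],
                 cor(m[, "a"], m[, "b"], method = "spearman"),
                 tolerance = 1e-12)

    m3 <- cbind(m, flat = 1)
    expect_warning(res3 <- correlationMatrix(m3), "flat")
    expect_true(all(is.na(res3$r["flat", ])))
})

test_that("least squares recovers exact and noisy relationships", {
    x <- c(1, 2, 3, 4, 5)
    fit <- suppressWarnings(olsFit(x, 2 * x + 1))  # perfect-fit warning
    expect_equal(fit$slope, 2, tolerance = 1e-12)
    expect_equal(fit$intercept, 1, tolerance = 1e-12)
    expect_equal(fit$r2, 1, tolerance = 1e-12)

    set.seed(6)
    xx <- rnorm(1000); yy <- rnorm(1000)   # independent by construction
    null_fit <- olsFit(xx, yy)
    expect_lt(abs(null_fit$slope), 0.1)
    expect_lt(null_fit$r2, 0.02)

    # normal-equations oracle
    x2 <- rnorm(40); y2 <- 1.5 * x2 + rnorm(40)
    f2 <- olsFit(x2, y2)
    X <- cbind(1, x2)
    beta <- solve(crossprod(X), crossprod(X, y2))
    expect_equal(c(f2$intercept, f2$slope), as.numeric(beta),
                 tolerance = 1e-10)
    expect_error(olsFit(x, rep(2, 5)),
                 class = "rhizofun_degenerate_response")
})

test_that("Mantel statistics agree with vegan and honor invariances", {
    set.seed(3)
    d1 <- dist(matrix(rnorm(9 * 3), 9))
    d2 <- dist(matrix(rnorm(9 * 3), 9))
    mine <- mantelTest(d1, d2, n_perm = 199, seed = 4)
    ref <- vegan::mantel(d1, d2, permutations = 199)
    expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)

    ident <- mantelTest(d1, d1, n_perm = 999, seed = 1)
    expect_equal(ident$r, 1)
    expect_equal(ident$p, 1 / 1000)

    perm <- sample(9)
    m1 <- as.matrix(d1)[perm, perm]; m2 <- as.matrix(d2)[perm, perm]
    expect_equal(mantelTest(m1, m2, n_perm = 11, seed = 1)$r, mine$r,
                 tolerance = 1e-12)
    expect_error(mantelTest(d1, dist(matrix(rnorm(8 * 3), 8))),
                 "same samples")
})

test_that("random-forest importance singles out the true driver", {
    set.seed(10)
    feats <- data.frame(signal = rnorm(40), noise1 = rnorm(40),
                        noise2 = rnorm(40), noise3 = rnorm(40))
    y <- feats$signal + rnorm(40, 0, 0.05)
    imp <- rfImportance(feats, y, seed = 99)
    expect_equal(names(which.max(imp)), "signal")
    expect_gt(imp["signal"], 5 * max(abs(imp[c("noise1", "noise2",
                                               "noise3")])))
    imp2 <- rfImportance(feats, y, seed = 99)
    expect_identical(imp, imp2)
    expect_error(rfImportance(feats, rep(1, 40)), "constant response")
})

test_that("path models recover a known chain and its Fisher's C", {
    set.seed(20)
    n <- 500
    a <- rnorm(n)
    b <- 0.8 * a + rnorm(n, 0, sqrt(1 - 0.64))
    c <- 0.6 * b + rnorm(n, 0, sqrt(1 - 0.36))
    dag <- data.frame(from = c("a", "b"), to = c("b", "c"))
    pm <- fitPathModel(dag, data.frame(a = a, b = b, c = c))
    co <- pathCoefficients(pm)
    expect_equal(co$estimate[co$response == "b"], 0.8, tolerance = 0.1)
    expect_equal(co$estimate[co$response == "c"], 0.6, tolerance = 0.1)
    eff <- pathEffects(pm)
    ac <- eff[eff$from == "a" & eff$to == "c", ]
    expect_equal(ac$direct, 0)
    expect_equal(ac$indirect, 0.48, tolerance = 0.1)
    expect_equal(ac$total, ac$direct + ac$indirect)

    fc <- fisherC(pm)
    expect_equal(fc$df, 2L)
    expect_equal(nrow(pm@claims), 1L)
    # closed form: C = -2 ln p and, at df = 2, model p = exp(-C/2)
    expect_equal(fc$C, -2 * log(pm@claims$p), tolerance = 1e-12)
    expect_equal(fc$p, exp(-fc$C / 2), tolerance = 1e-12)
    expect_gt(fc$p, 0.05)
})

test_that("saturated models have C = 0 with df 0 and p 1", {
    set.seed(21)
    d <- data.frame(a = rnorm(50))
    d$b <- d$a + rnorm(50)
    d$c <- d$a + d$b + rnorm(50)
    dag <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"))
    pm <- fitPathModel(dag, d)
    expect_equal(fisherC(pm), list(C = 0, df = 0L, p = 1))
})

test_that("total effects equal the matrix geometric-series oracle", {
    set.seed(22)
    n <- 200
    d <- data.frame(a = rnorm(n), e = rnorm(n))
    d$b <- 0.5 * d$a + 0.3 * d$e + rnorm(n, 0, 0.7)
    d$c <- 0.4 * d$b + 0.2 * d$a + rnorm(n, 0, 0.8)
    d$f <- 0.6 * d$c + rnorm(n, 0, 0.7)
    dag <- data.frame(from = c("a", "e", "b", "a", "c"),
                      to   = c("b", "b", "c", "c", "f"))
    pm <- fitPathModel(dag, d)
    oracle <- brute_total_effects(pm)
    eff <- pathEffects(pm)
    for (i in seq_len(nrow(eff)))
        expect_equal(eff$total[i], oracle[eff$from[i], eff$to[i]],
                     tolerance = 1e-10)
})

test_that("cyclic or collinear path models are rejected", {
    d <- data.frame(a = rnorm(30), b = rnorm(30))
    d$c <- d$a + d$b
    expect_error(fitPathModel(data.frame(from = c("a", "b"),
                                         to = c("b", "a")), d), "cycle")
    dd <- data.frame(a = rnorm(30))
    dd$b <- 2 * dd$a            # exactly collinear parents
    dd$c <- dd$a + rnorm(30)
    expect_error(fitPathModel(data.frame(from = c("a", "b"),
                                         to = c("c", "c")), dd),
                 "collinear")
})

test_that("Fisher's C p-values are uniform when the structure is true", {
    set.seed(30)
    pvals <- replicate(400, {
        n <- 60
        a <- rnorm(n)
        b <- 0.7 * a + rnorm(n, 0, 0.7)
        c <- 0.5 * b + rnorm(n, 0, 0.85)
        pm <- fitPathModel(data.frame(from = c("a", "b"), to = c("b", "c")),
                           data.frame(a = a, b = b, c = c))
        fisherC(pm)$p
    })
    expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value),
              0.01)
})
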