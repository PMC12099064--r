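test_that("Clopper-Pearson intervals match closed forms and binom.test", {
    ci <- clopperPearson(40, 48)
    expect_equal(unname(ci), c(0.6977776, 0.9251891), tolerance = 1e-6)
    expect_equal(unname(ci),
                 as.numeric(binom.test(40, 48)$conf.int), tolerance = 1e-9)

    ci <- clopperPearson(52, 52)
    expect_identical(ci[["upper"]], 1)
    expect_equal(ci[["lower"]], 0.9315178, tolerance = 1e-6)

    expect_identical(clopperPearson(0, 10)[["lower"]], 0)
    expect_error(clopperPearson(5, 4), "x <= n")
})

test_that("Clopper-Pearson brackets the estimate and narrows with n", {
    for (n in c(5, 20, 80)) {
        for (x in 0:n) {
            ci <- clopperPearson(x, n)
            expect_lte(ci[["lower"]], x / n)
            expect_gte(ci[["upper"]], x / n)
        }
    }
    w <- function(x, n) diff(unname(clopperPearson(x, n)))
    expect_gt(w(4, 10), w(40, 100))
    expect_gt(w(40, 100), w(400, 1000))
})

test_that("2x2 Fisher matches enumeration-derived values", {
    # margins (2,2)x(2,2): three tables with probabilities {1,4,1}/6
    expect_equal(fisherExact2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3,
                 tolerance = 1e-9)
    expect_equal(fisherExact2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1,
                 tolerance = 1e-9)
    expect_equal(fisherExact2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
                 tolerance = 1e-9)
    # zero margin convention
    expect_equal(fisherExact2x2(matrix(c(0, 0, 3, 4), 2))$p_value, 1)
    # boundary odds ratios are allowed
    expect_equal(fisherExact2x2(matrix(c(5, 0, 0, 5), 2))$odds_ratio, Inf)
})

test_that("r x c Fisher agrees with the 2x2 test and known symmetries", {
    set.seed(21)
    for (i in 1:25) {
        x <- randomCountTable(30)
        if (!all(dim(x) == 2)) x <- x[1:2, 1:2]
        expect_equal(fisherExactRxC(x), fisherExact2x2(x)$p_value,
                     tolerance = 1e-7)
    }
    expect_equal(fisherExactRxC(matrix(1, 2, 3)), 1, tolerance = 1e-9)
    expect_error(fisherExactRxC(matrix(100, 2, 2)), "too large")
    expect_error(fisherExactRxC(matrix(1:3, 1)), "r, c >= 2")
})

test_that("r x c Fisher agrees with an independent exact implementation", {
    set.seed(22)
    for (i in 1:40) {
        x <- randomCountTable(40)
        expect_equal(fisherExactRxC(x), fisher.test(x)$p.value,
                     tolerance = 1e-6, label = paste(dim(x), collapse = "x"))
    }
})

test_that("Mann-Whitney exact and approximate paths", {
    mw <- mannWhitney(c(1, 2), c(3, 4))
    expect_equal(mw$U, 0)
    expect_equal(mw$p_value, 1 / 3, tolerance = 1e-9)

    x <- c(3.2, 5.1, 7.4, 2.2, 9.9)
    mw <- mannWhitney(x, x)   # tied multisets force the approximate path
    expect_equal(mw$U, length(x)^2 / 2)
    expect_equal(mw$p_value, 1)

    set.seed(31)
    a <- rnorm(50); b <- rnorm(50, mean = 2)
    expect_lt(mannWhitney(b, a)$p_value, 0.001)
    expect_error(mannWhitney(numeric(0), 1), "nonempty")
})

test_that("Kruskal-Wallis behaviour and two-group consistency", {
    set.seed(32)
    a <- rnorm(10); b <- rnorm(10, 1)
    kw <- kruskalWallis(list(a, b))
    mw <- mannWhitney(a, b)
    expect_lt(abs(kw$p_value - mw$p_value), 0.02)

    same <- kruskalWallis(list(c(2, 2, 2), c(2, 2)))
    expect_equal(same$H, 0)
    expect_equal(same$p_value, 1)

    g <- list(rnorm(20), rnorm(20, 1.5), rnorm(20, 3))
    expect_lt(kruskalWallis(g)$p_value, 0.01)
    expect_error(kruskalWallis(list(1:3)), "two")
})

test_that("ROC AUC matches brute-force pair counting", {
    expect_equal(rocAuc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
    expect_equal(rocAuc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
    # with one tie across classes: pairs (3,1),(3,2),(4,1),(4,2) concordant
    # would give 1; scores c(1,2,2,4) tie one pair -> 7/8
    expect_equal(rocAuc(c(1, 2, 2, 4), c(0, 0, 1, 1)), 0.875)
    set.seed(41)
    for (i in 1:20) {
        sc <- round(rnorm(30), 1)          # rounding induces ties
        lab <- rbinom(30, 1, 0.4)
        if (sum(lab) == 0 || sum(lab) == 30) next
        expect_equal(rocAuc(sc, lab), oracleAuc(sc, lab), tolerance = 1e-12)
    }
    # tie-free data: AUC equals U / (n_pos * n_neg)
    set.seed(42)
    sc <- rnorm(40); lab <- rep(c(0, 1), 20)
    U <- mannWhitney(sc[lab == 1], sc[lab == 0])$U
    expect_equal(rocAuc(sc, lab), U / (20 * 20), tolerance = 1e-12)
    expect_error(rocAuc(1:5, rep(1, 5)), "both label classes")
})

test_that("ROC AUC agrees with pROC", {
    set.seed(43)
    sc <- rnorm(60)
    lab <- rbinom(60, 1, 0.5)
    expect_equal(rocAuc(sc, lab),
                 as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
})
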