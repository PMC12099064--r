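test_that("score matches the term-by-term Beta log-ratio oracle", {
    panel <- toyPanel()
    model <- toyModel(panel)
    features <- data.frame(marker = c("T1", "T2"),
                           del_freq = c(0.4, 0.5),
                           allelic_bias = c(0.9, 0.8),
                           stringsAsFactors = FALSE)
    expected <- oracleScore(features, model@params, model@n_train)
    expect_equal(msiScore(features, model), expected, tolerance = 1e-12)
    # the del_freq-only part is also checkable in closed form:
    # bias conditionals are identical so they cancel exactly
    shrink <- function(x, n) (x * n + 0.5) / (n + 1)
    byHand <- sum(dbeta(shrink(c(0.4, 0.5), 1e6), 10, 10, log = TRUE) -
                  dbeta(shrink(c(0.4, 0.5), 1e6), 2, 38, log = TRUE))
    expect_equal(msiScore(features, model), byHand, tolerance = 1e-9)
})

test_that("identical class conditionals give the prior as the score", {
    panel <- toyPanel()
    grid <- expand.grid(marker = markerNames(panel),
                        class = c("MSS", "MSI-H"),
                        feature = c("del_freq", "allelic_bias"),
                        stringsAsFactors = FALSE)
    grid$alpha <- 3; grid$beta <- 7
    m0 <- MsiModel(grid, prior_log_odds = 0)
    m2 <- MsiModel(grid, prior_log_odds = 2.5)
    features <- data.frame(marker = "T1", del_freq = 0.3,
                           allelic_bias = 0.6)
    expect_equal(msiScore(features, m0), 0)
    expect_equal(msiScore(features, m2), 2.5)
})

test_that("score is additive: uninformative markers change nothing", {
    panel <- toyPanel()
    model <- toyModel(panel)
    f2 <- data.frame(marker = c("T1", "T2"), del_freq = c(0.4, 0.5),
                     allelic_bias = c(0.9, 0.8))
    f1 <- f2[1, ]
    # T2's contribution equals its own single-marker score
    expect_equal(msiScore(f2, model),
                 msiScore(f1, model) + msiScore(f2[2, ], model),
                 tolerance = 1e-12)
})

test_that("swapping class labels negates the score", {
    panel <- toyPanel()
    model <- toyModel(panel)
    swapped <- model@params
    swapped$class <- ifelse(swapped$class == "MSS", "MSI-H", "MSS")
    modelSw <- MsiModel(swapped)
    features <- data.frame(marker = c("T1", "T2"), del_freq = c(0.15, 0.6),
                           allelic_bias = c(0.5, 0.95))
    expect_equal(msiScore(features, modelSw), -msiScore(features, model),
                 tolerance = 1e-12)
})

test_that("score is monotone in del_freq where the density ratio increases", {
    # MSI-H Beta(10,10) vs MSS Beta(2,38): the likelihood ratio is
    # x^8 (1-x)^-28, increasing on (0,1)
    panel <- toyPanel()
    model <- toyModel(panel)
    grid <- seq(0.05, 0.95, by = 0.05)
    scores <- vapply(grid, function(x)
        msiScore(data.frame(marker = "T1", del_freq = x,
                            allelic_bias = 0.5), model), numeric(1))
    expect_true(all(diff(scores) > 0))
})

test_that("training recovers the simulator's class means", {
    panel <- defaultPanel()
    cfg <- simulationConfig(seed = 42, n_mss = 15, n_msih = 15,
                            n_msh6like = 0, depth_mean = 500)
    sim <- simulateCohort(cfg, panel)
    model <- fitMsiModel(sim$spectra, sim$truth$true_class, panel)
    m <- panelMarkers(panel)
    s <- cfg$stutter_rate
    for (i in seq_len(nrow(m))) {
        for (cls in c("MSS", "MSI-H")) {
            f <- if (cls == "MSS") 0 else cfg$somatic_fraction
            trueMean <- f + (1 - f) * (1 - (1 - s)^m$ref_length[i])
            row <- model@params[model@params$marker == m$name[i] &
                                model@params$class == cls &
                                model@params$feature == "del_freq", ]
            fitted <- row$alpha / (row$alpha + row$beta)
            expect_lt(abs(fitted - trueMean), 0.05)
        }
    }
    # qualitative direction: MSS deletion conditional concentrated near 0
    mss <- model@params[model@params$class == "MSS" &
                        model@params$feature == "del_freq", ]
    expect_true(all(mss$alpha / (mss$alpha + mss$beta) < 0.15))
})

test_that("training validates labels, class sizes and marker coverage", {
    panel <- toyPanel()
    sp <- replicate(10, toySpectra(list(T1 = c(`20` = 50, `18` = 5),
                                        T2 = c(`25` = 50))),
                    simplify = FALSE)
    labels <- rep(c("MSS", "MSI-H"), each = 5)
    expect_s4_class(fitMsiModel(sp, labels, panel), "MsiModel")
    expect_error(fitMsiModel(sp, rep("MSS", 10), panel), "at least 5")
    expect_error(fitMsiModel(sp, replace(labels, 1, "weird"), panel),
                 "labels")
    # marker with no observations anywhere is named in the error
    noT2 <- replicate(10, toySpectra(list(T1 = c(`20` = 50))),
                      simplify = FALSE)
    expect_error(fitMsiModel(noT2, labels, panel), "T2")
})

test_that("identical feature sets in both classes score the prior", {
    panel <- toyPanel()
    sp <- replicate(12, toySpectra(list(T1 = c(`20` = 45, `18` = 5),
                                        T2 = c(`25` = 40, `22` = 10))),
                    simplify = FALSE)
    # same samples labelled both ways -> identical per-class parameters
    model <- fitMsiModel(c(sp, sp),
                         rep(c("MSS", "MSI-H"), each = 12), panel)
    f <- computeFeatures(sp[[1]], panel)
    expect_equal(msiScore(f, model), model@prior_log_odds, tolerance = 1e-9)
})

test_that("classification thresholds, band and repeat rule", {
    expect_equal(msiCall(classifyMsi(6, qc = TRUE)), "MSI-H")
    expect_false(classifyMsi(6, qc = TRUE)@needs_repeat)
    expect_equal(msiCall(classifyMsi(-7, qc = TRUE)), "MSS")

    # inside the band without a repeat: provisional call, repeat requested
    r <- classifyMsi(3, qc = TRUE)
    expect_equal(msiCall(r), "MSI-H")
    expect_true(r@needs_repeat)

    # conflicting repeat -> uncertain with reported score 0
    r <- classifyMsi(3, qc = TRUE, repeat_score = -2)
    expect_equal(msiCall(r), "uncertain")
    expect_equal(resultScore(r), 0)

    # concordant repeat confirms the call
    r <- classifyMsi(-3, qc = TRUE, repeat_score = -4)
    expect_equal(msiCall(r), "MSS")
    expect_false(r@needs_repeat)

    # QC failure dominates everything
    expect_equal(msiCall(classifyMsi(25, qc = FALSE)), "fail")

    # score exactly 0 without repeat: uncertain, repeat requested
    r <- classifyMsi(0, qc = TRUE)
    expect_equal(msiCall(r), "uncertain")
    expect_true(r@needs_repeat)

    # degenerate band 0: every nonzero score is called outright
    expect_false(classifyMsi(0.01, qc = TRUE, band = 0)@needs_repeat)
})

test_that("model JSON round trip preserves scores exactly", {
    panel <- toyPanel()
    model <- toyModel(panel, n_train = c(MSS = 20, `MSI-H` = 15))
    f <- withr::local_tempfile(fileext = ".json")
    saveModel(model, f)
    back <- loadModel(f)
    features <- data.frame(marker = c("T1", "T2"), del_freq = c(0.2, 0.7),
                           allelic_bias = c(0.4, 1.0))
    expect_equal(msiScore(features, back), msiScore(features, model),
                 tolerance = 1e-9)

    # truncated file fails to load
    txt <- readLines(f)
    half <- withr::local_tempfile(fileext = ".json")
    writeLines(substr(paste(txt, collapse = ""), 1, 50), half)
    expect_error(loadModel(half), "unreadable|schema")

    # a model missing a marker refuses to score it
    features2 <- rbind(features,
                       data.frame(marker = "T3", del_freq = 0.1,
                                  allelic_bias = 0.2))
    expect_error(msiScore(features2, model), "T3")
})
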