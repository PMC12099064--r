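# Shared fixtures and independent oracles for the test suite.

# Two-marker toy panel with poly-A repeats and distinct 12-nt flanks.
toyPanel <- function() {
    MarkerPanel(data.frame(
        name = c("T1", "T2"),
        repeat_unit = "A",
        ref_length = c(20L, 25L),
        flank5 = c("TTGATTAACCCG", "GACATGGCGCTT"),
        flank3 = c("AACTTCGAAGAG", "ACTGCCGCATCC"),
        stringsAsFactors = FALSE), version = "toy")
}

# SampleSpectra from a list like list(T1 = c(`20` = 90, `18` = 10)).
toySpectra <- function(counts, id = "S1", panel = toyPanel()) {
    full <- setNames(vector("list", length(markerNames(panel))),
                     markerNames(panel))
    for (nm in names(counts)) full[[nm]] <- counts[[nm]]
    full[vapply(full, is.null, logical(1))] <-
        list(setNames(integer(0), character(0)))
    SampleSpectra(id, full)
}

# Toy model: MSS del_freq ~ Beta(2,38), MSI-H del_freq ~ Beta(10,10); the
# allelic-bias conditionals are identical across classes so only del_freq
# carries signal. Very large n_train makes shrinkage negligible but the
# oracle applies it anyway.
toyModel <- function(panel = toyPanel(), n_train = c(MSS = 1e6, `MSI-H` = 1e6)) {
    grid <- expand.grid(marker = markerNames(panel),
                        class = c("MSS", "MSI-H"),
                        feature = c("del_freq", "allelic_bias"),
                        stringsAsFactors = FALSE)
    grid$alpha <- ifelse(grid$feature == "allelic_bias", 2,
                         ifelse(grid$class == "MSS", 2, 10))
    grid$beta <- ifelse(grid$feature == "allelic_bias", 2,
                        ifelse(grid$class == "MSS", 38, 10))
    MsiModel(grid, prior_log_odds = 0, n_train = n_train)
}

# Independent scoring oracle: explicit term-by-term sum of shrunk Beta
# log-density differences, written without reference to msiScore internals.
oracleScore <- function(features, params, n_train, prior = 0) {
    shrink <- function(x, n) (x * n + 0.5) / (n + 1)
    s <- prior
    for (i in seq_len(nrow(features))) {
        for (ft in c("del_freq", "allelic_bias")) {
            for (cls in c("MSI-H", "MSS")) {
                row <- params[params$marker == features$marker[i] &
                              params$class == cls & params$feature == ft, ]
                d <- max(dbeta(shrink(features[[ft]][i], n_train[[cls]]),
                               row$alpha, row$beta), 1e-300)
                s <- s + if (cls == "MSI-H") log(d) else -log(d)
            }
        }
    }
    s
}

# O(n^2) AUC oracle: explicit concordant/tied pair counting.
oracleAuc <- function(scores, labels) {
    pos <- scores[as.logical(labels)]
    neg <- scores[!as.logical(labels)]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

# Random non-degenerate r x c count table with total at most nmax.
randomCountTable <- function(nmax = 40) {
    repeat {
        r <- sample(2:3, 1)
        cc <- sample(2:3, 1)
        n <- sample(4:nmax, 1)
        x <- matrix(rmultinom(1, n, prob = runif(r * cc, 0.2, 1)), r, cc)
        if (all(rowSums(x) > 0) && all(colSums(x) > 0)) return(x)
    }
}

# Random SampleSpectra on the default panel (for inversion properties).
randomSpectra <- function(panel, id = "R1") {
    nm <- markerNames(panel)
    counts <- setNames(vector("list", length(nm)), nm)
    for (mk in sample(nm, sample(1:4, 1))) {
        lens <- sample(0:32, sample(1:4, 1))
        counts[[mk]] <- setNames(sample(1:15, length(lens), replace = TRUE),
                                 lens)
    }
    counts[vapply(counts, is.null, logical(1))] <-
        list(setNames(integer(0), character(0)))
    SampleSpectra(id, counts)
}

expect_spectra_equal <- function(a, b) {
    expect_identical(markerNames(a), markerNames(b))
    for (mk in markerNames(a)) {
        va <- spectrumCounts(a, mk)
        vb <- spectrumCounts(b, mk)
        expect_identical(as.integer(va), as.integer(vb), label = mk)
        expect_identical(names(va), names(vb), label = mk)
    }
}
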