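#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval from Beta quantiles: lower bound the (1-conf)/2
#' quantile of Beta(x, n-x+1) (0 when x = 0), upper bound the 1-(1-conf)/2
#' quantile of Beta(x+1, n-x) (1 when x = n).
#'
#' @param x number of successes.
#' @param n number of trials (>= 1).
#' @param conf confidence level (default 0.95).
#' @return numeric vector \code{c(lower, upper)} of fractions.
#' @examples
#' round(100 * clopperPearson(40, 48))  # 70 93
#' @export
clopperPearson <- function(x, n, conf = 0.95) {
    if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
        n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
        stopValidation("need integers 0 <= x <= n with n >= 1")
    if (conf <= 0 || conf >= 1)
        stopValidation("conf must be in (0,1)")
    a <- 1 - conf
    lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
    c(lower = lower, upper = upper)
}

.checkCountTable <- function(x) {
    x <- as.matrix(x)
    if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
        stopValidation("contingency table must hold non-negative integers")
    storage.mode(x) <- "double"
    x
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the conventional rule: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the observed table's probability. The odds ratio is the
#' conditional maximum-likelihood estimate of the noncentral hypergeometric
#' (0 and Inf occur at boundary tables); the unconditional sample odds ratio
#' is reported alongside.
#'
#' @param table a 2x2 matrix of non-negative integer counts.
#' @return list with \code{p_value}, \code{odds_ratio} (conditional MLE) and
#'   \code{sample_odds_ratio}.
#' @examples
#' fisherExact2x2(matrix(c(2, 0, 0, 2), 2))$p_value  # 1/3
#' @export
fisherExact2x2 <- function(table) {
    x <- .checkCountTable(table)
    if (!all(dim(x) == c(2L, 2L)))
        stopValidation("fisherExact2x2 needs a 2x2 table")
    if (any(rowSums(x) == 0) || any(colSums(x) == 0))
        return(list(p_value = 1.0, odds_ratio = NA_real_,
                    sample_odds_ratio = NA_real_))
    ft <- stats::fisher.test(x)
    list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
         sample_odds_ratio = (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1]))
}

#' Fisher's exact test for an r x c table by full enumeration
#'
#' Enumerates every table with the observed row and column margins,
#' accumulating the multivariate hypergeometric probability of each table
#' whose probability does not exceed the observed table's (within relative
#' tolerance 1e-7). Exact and deterministic; refuses tables beyond the
#' enumeration budget rather than falling back to an approximation.
#'
#' @param table an r x c matrix of non-negative integer counts, r, c >= 2.
#' @param budget maximum table total n for enumeration (default 200).
#' @return two-sided p-value.
#' @examples
#' fisherExactRxC(matrix(1, 2, 3))  # 1
#' @export
fisherExactRxC <- function(table, budget = 200) {
    x <- .checkCountTable(table)
    if (nrow(x) < 2L || ncol(x) < 2L)
        stopValidation("need an r x c table with r, c >= 2")
    n <- sum(x)
    if (n > budget)
        stopValidation("table too large for exact enumeration (n = ", n,
                       " exceeds budget ", budget, ")")
    # zero margins carry no information; drop them
    x <- x[rowSums(x) > 0, , drop = FALSE]
    x <- x[, colSums(x) > 0, drop = FALSE]
    if (nrow(x) < 2L || ncol(x) < 2L || n == 0) return(1.0)
    rs <- rowSums(x)
    cs <- colSums(x)
    r <- length(rs)
    cc <- length(cs)
    logConst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
    logObs <- logConst - sum(lgamma(x + 1))
    threshold <- logObs + log1p(1e-7)
    total <- 0

    enumRow <- function(i, colrem, acc) {
        if (i == r) {                       # last row forced by col margins
            lp <- logConst + acc - sum(lgamma(colrem + 1))
            if (lp <= threshold) total <<- total + exp(lp)
            return(invisible())
        }
        fillCell(i, 1L, rs[i], colrem, acc)
    }
    fillCell <- function(i, j, rowrem, colrem, acc) {
        if (j == cc) {
            if (rowrem <= colrem[cc]) {
                colrem[cc] <- colrem[cc] - rowrem
                enumRow(i + 1L, colrem, acc - lgamma(rowrem + 1))
            }
            return(invisible())
        }
        restCap <- sum(colrem[(j + 1L):cc])
        lo <- max(0, rowrem - restCap)
        hi <- min(rowrem, colrem[j])
        if (lo > hi) return(invisible())
        for (v in lo:hi) {
            colrem2 <- colrem
            colrem2[j] <- colrem[j] - v
            fillCell(i, j + 1L, rowrem - v, colrem2, acc - lgamma(v + 1))
        }
    }
    enumRow(1L, cs, 0)
    min(max(total, 0), 1)
}

#' Mann-Whitney U test
#'
#' U counts the (x, y) pairs with x above y (ties half-weighted). The
#' p-value is exact (full permutation distribution) when the combined sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y numeric vectors, both nonempty.
#' @return list with \code{U} and \code{p_value} (two-sided).
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mannWhitney <- function(x, y) {
    if (!length(x) || !length(y))
        stopValidation("both groups must be nonempty")
    ties <- any(duplicated(c(x, y)))
    exact <- (length(x) + length(y) <= 12L) && !ties
    wt <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Kruskal-Wallis rank test
#'
#' H with tie correction; p from the chi-squared approximation with k-1
#' degrees of freedom. When every value is identical H is 0 and p is 1.
#'
#' @param groups list of two or more nonempty numeric vectors.
#' @return list with \code{H} and \code{p_value}.
#' @export
kruskalWallis <- function(groups) {
    if (length(groups) < 2L || any(!lengths(groups)))
        stopValidation("need at least two nonempty groups")
    vals <- unlist(groups, use.names = FALSE)
    if (length(unique(vals)) == 1L)
        return(list(H = 0, p_value = 1))
    kt <- stats::kruskal.test(groups)
    list(H = unname(kt$statistic), p_value = kt$p.value)
}

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the proportion of (positive, negative) score
#' pairs in which the positive scores higher, counting ties as half.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels (logical, 0/1, or a two-level factor; the
#'   higher level / TRUE / 1 is the positive class).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
    if (is.factor(labels)) labels <- as.integer(labels) - 1L
    labels <- as.logical(labels)
    if (anyNA(labels) || anyNA(scores))
        stopValidation("scores and labels must be complete")
    nPos <- sum(labels)
    nNeg <- sum(!labels)
    if (nPos == 0L || nNeg == 0L)
        stopValidation("both label classes must be present")
    r <- rank(scores, ties.method = "average")
    (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
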