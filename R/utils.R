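# Condition helpers: validation errors get their own class so callers (and
# the command-line wrapper) can map them to a distinct exit status.

stopValidation <- function(...) {
    stop(errorCondition(paste0(...), class = c("seqmsi_validation_error",
                                               "error", "condition")))
}

stopUsage <- function(...) {
    stop(errorCondition(paste0(...), class = c("seqmsi_usage_error",
                                               "error", "condition")))
}

# Lower median: for even n, the lower of the two central order statistics.
lowerMedian <- function(x) {
    n <- length(x)
    if (n == 0L) return(0L)
    unname(sort(x)[ceiling(n / 2)])
}

# Shrink a proportion away from {0,1}: x -> (x*n + 0.5) / (n + 1).
shrinkProportion <- function(x, n) (x * n + 0.5) / (n + 1)
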