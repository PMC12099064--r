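# Reference-cohort cross-tabulations: published counts from a consecutive
# sebaceous-tumour screening cohort (n = 107), shipped as plain-text
# fixtures so the concordance statistics can be recomputed without any
# sequencing step.

#' Reference cohort: IHC classification by tumour type
#'
#' Counts of sebaceous tumours by MMR IHC class (MMRd, equivocal, MMRp, NA)
#' and tumour type (sebaceoma, adenoma, carcinoma) in the reference
#' screening cohort of 107 consecutive cases.
#'
#' @return integer matrix, IHC classes as rows, tumour types as columns.
#' @export
referenceIhcByType <- function() {
    path <- system.file("extdata", "ihc_by_tumour_type.tsv",
                        package = "seqMSI", mustWork = TRUE)
    # "NA" is a real class token (uninterpretable IHC), not a missing value
    df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
    m <- as.matrix(df[, -1L])
    rownames(m) <- df$ihc_class
    m
}

#' Reference cohort: MSI calls by IHC staining pattern
#'
#' Counts of MSI classifications (MSS, uncertain, MSI-H) by detailed MMR IHC
#' staining pattern in the reference cohort (n = 107).
#'
#' @return data.frame with columns \code{pattern}, \code{ihc_class},
#'   \code{mss}, \code{uncertain}, \code{msih}.
#' @export
referenceMsiByPattern <- function() {
    path <- system.file("extdata", "msi_by_ihc_pattern.tsv",
                        package = "seqMSI", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}

# Expand the pattern x call count table into one row per sample with
# synthetic ids, so the concordance machinery runs on the published counts.
.expandReferencePairs <- function(pat = referenceMsiByPattern()) {
    rows <- list()
    k <- 0L
    for (i in seq_len(nrow(pat))) {
        for (call in c("MSS", "uncertain", "MSI-H")) {
            cnt <- pat[i, c(MSS = "mss", uncertain = "uncertain",
                            `MSI-H` = "msih")[[call]]]
            if (cnt == 0) next
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = sprintf("REF%03d", k + seq_len(cnt)),
                mmr_class = pat$ihc_class[i], call = call,
                pattern = pat$pattern[i], stringsAsFactors = FALSE)
            k <- k + cnt
        }
    }
    do.call(rbind, rows)
}

#' Recompute the reference-cohort concordance statistics
#'
#' Re-derives, from the shipped cross-tabulation fixtures, the headline
#' statistics of the reference screening cohort: sensitivity and specificity
#' of MSI calling against IHC (with Clopper-Pearson intervals), MMR
#' deficiency and MSI class frequencies, the distribution of staining
#' patterns among MMR-deficient tumours, and the Fisher exact association
#' between IHC class and tumour type (3x3 table, NA cases excluded).
#'
#' @param conf confidence level (default 0.95).
#' @return list with components \code{concordance} (the
#'   [diagnosticSummary()] output), \code{frequencies} (MMRd, MSI-H, MSS
#'   frequencies with numerators/denominators and CIs), \code{patterns}
#'   (pattern frequencies among MMRd cases) and \code{tumour_type_fisher}
#'   (p-value and the 3x3 table used).
#' @export
referenceStatistics <- function(conf = 0.95) {
    pairs <- .expandReferencePairs()
    conc <- diagnosticSummary(pairs[, c("sample_id", "call")],
                              pairs[, c("sample_id", "mmr_class")],
                              conf = conf)

    binomStat <- function(x, n)
        list(estimate = x / n, x = x, n = n, ci = clopperPearson(x, n, conf))
    ihcTab <- referenceIhcByType()
    nIhc <- sum(ihcTab) - sum(ihcTab["NA", ])
    freqs <- list(
        mmrd = binomStat(sum(ihcTab["MMRd", ]), nIhc),
        msih = binomStat(sum(pairs$call == "MSI-H"), nrow(pairs)),
        mss = binomStat(sum(pairs$call == "MSS"), nrow(pairs)))

    pat <- referenceMsiByPattern()
    pat$total <- pat$mss + pat$uncertain + pat$msih
    mmrd <- pat[pat$ihc_class == "MMRd", ]
    nMmrd <- sum(mmrd$total)
    patCount <- function(patterns) sum(mmrd$total[mmrd$pattern %in% patterns])
    patterns <- list(
        msh2_msh6_coloss = binomStat(patCount("MSH2/MSH6 loss"), nMmrd),
        mlh1_pms2_coloss = binomStat(
            patCount(c("MLH1/PMS2 loss", "MLH1 eq., PMS2 loss")), nMmrd),
        isolated_msh6 = binomStat(
            patCount(c("MSH6 loss", "MSH2 eq., MSH6 loss")), nMmrd))

    tab3 <- ihcTab[c("MMRd", "equivocal", "MMRp"), ]
    fisherP <- fisherExactRxC(tab3)

    list(concordance = conc, frequencies = freqs, patterns = patterns,
         tumour_type_fisher = list(p_value = fisherP, table = tab3))
}
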