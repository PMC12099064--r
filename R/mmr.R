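.IHC_TOKENS <- c("retained", "loss", "equivocal", "uninterpretable")
.PROTEINS <- c("mlh1", "pms2", "msh2", "msh6")

#' Derive the MMR class from four-protein IHC statuses
#'
#' Deterministic rule over the per-protein staining statuses of MLH1, PMS2,
#' MSH2 and MSH6: any uninterpretable protein makes the sample "NA"
#' (technically unassessable); otherwise any clear loss makes it "MMRd"
#' (so equivocal staining in one protein with loss in another still counts
#' as deficient); otherwise any equivocal staining makes it "equivocal";
#' otherwise "MMRp".
#'
#' @param mlh1,pms2,msh2,msh6 character vectors of equal length with values
#'   in \code{retained, loss, equivocal, uninterpretable}.
#' @return character vector with values in \code{MMRd, equivocal, MMRp, NA}
#'   (the literal token "NA", not a missing value).
#' @examples
#' deriveMmrClass("equivocal", "loss", "retained", "retained")  # "MMRd"
#' @export
deriveMmrClass <- function(mlh1, pms2, msh2, msh6) {
    st <- cbind(mlh1, pms2, msh2, msh6)
    bad <- setdiff(unique(as.vector(st)), .IHC_TOKENS)
    if (length(bad))
        stopValidation("unknown IHC status token(s): ",
                       paste(bad, collapse = ", "))
    apply(st, 1L, function(r) {
        if (any(r == "uninterpretable")) "NA"
        else if (any(r == "loss")) "MMRd"
        else if (any(r == "equivocal")) "equivocal"
        else "MMRp"
    })
}

#' Read a per-sample IHC table
#'
#' CSV with columns \code{sample_id, mlh1, pms2, msh2, msh6}; statuses from
#' \code{retained, loss, equivocal, uninterpretable}.
#'
#' @param path path to the CSV.
#' @return data.frame with the five columns plus a derived \code{mmr_class}.
#' @export
readIhcCsv <- function(path) {
    if (!file.exists(path))
        stopValidation("IHC file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", .PROTEINS)
    if (!all(need %in% names(df)))
        stopValidation("IHC CSV needs columns: ", paste(need, collapse = ", "))
    df$mmr_class <- deriveMmrClass(df$mlh1, df$pms2, df$msh2, df$msh6)
    df
}

#' MSI vs IHC diagnostic concordance
#'
#' Cross-tabulates per-sample MSI calls against MMR IHC classes and computes
#' the diagnostic performance of MSI calling with IHC as the reference.
#' Sensitivity is the fraction of MMR-deficient samples called MSI-H;
#' specificity the fraction of MMR-proficient samples called MSS. Both are
#' computed on the conclusively classified samples only: IHC classes
#' "equivocal" and "NA" and MSI calls "uncertain" and "fail" are excluded
#' from the denominators (they remain in the cross-tabulation). Exact
#' Clopper-Pearson confidence intervals are attached.
#'
#' @param calls data.frame with columns \code{sample_id} and \code{call}
#'   (values MSI-H, MSS, uncertain, fail).
#' @param ihc data.frame with columns \code{sample_id} and \code{mmr_class}
#'   (values MMRd, equivocal, MMRp, NA), e.g. from [readIhcCsv()] or
#'   [deriveMmrClass()].
#' @param conf confidence level for the intervals (default 0.95).
#' @return list with \code{crosstab} (MMR class x MSI call contingency
#'   table covering every input pair), \code{sensitivity} and
#'   \code{specificity} (each a list with \code{estimate}, \code{x},
#'   \code{n}, \code{ci}; estimate is NA when the denominator is empty),
#'   and \code{n} (number of paired samples).
#' @export
diagnosticSummary <- function(calls, ihc, conf = 0.95) {
    if (!all(c("sample_id", "call") %in% names(calls)))
        stopValidation("calls needs columns sample_id, call")
    if (!all(c("sample_id", "mmr_class") %in% names(ihc)))
        stopValidation("ihc needs columns sample_id, mmr_class")
    missingIhc <- setdiff(calls$sample_id, ihc$sample_id)
    missingMsi <- setdiff(ihc$sample_id, calls$sample_id)
    if (length(missingIhc) || length(missingMsi))
        stopValidation("unpaired sample ids: ",
                       paste(c(missingIhc, missingMsi), collapse = ", "))
    if (anyDuplicated(calls$sample_id) || anyDuplicated(ihc$sample_id))
        stopValidation("duplicate sample ids")
    mmr <- ihc$mmr_class[match(calls$sample_id, ihc$sample_id)]
    call <- calls$call
    if (!all(call %in% c("MSI-H", "MSS", "uncertain", "fail")))
        stopValidation("unknown MSI call value")
    if (!all(mmr %in% c("MMRd", "equivocal", "MMRp", "NA")))
        stopValidation("unknown MMR class value")
    crosstab <- table(
        mmr_class = factor(mmr, levels = c("MMRd", "equivocal", "MMRp", "NA")),
        msi_call = factor(call, levels = c("MSS", "uncertain", "MSI-H", "fail")))
    conclusive <- call %in% c("MSI-H", "MSS")
    binomStat <- function(x, n) {
        if (n == 0)
            return(list(estimate = NA_real_, x = 0L, n = 0L,
                        ci = c(lower = NA_real_, upper = NA_real_)))
        list(estimate = x / n, x = x, n = n, ci = clopperPearson(x, n, conf))
    }
    nD <- sum(mmr == "MMRd" & conclusive)
    xD <- sum(mmr == "MMRd" & call == "MSI-H")
    nP <- sum(mmr == "MMRp" & conclusive)
    xP <- sum(mmr == "MMRp" & call == "MSS")
    list(crosstab = crosstab,
         sensitivity = binomStat(xD, nD),
         specificity = binomStat(xP, nP),
         n = length(call))
}
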