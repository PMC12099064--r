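#' Per-marker deletion features
#'
#' For every marker with non-zero depth, computes the two features the MSI
#' classifier uses:
#' \describe{
#'   \item{del_freq}{proportion of assigned reads with repeat length strictly
#'     below the sample-specific reference length.}
#'   \item{allelic_bias}{among deletion reads, the proportion carrying the
#'     single most frequent deleted length; 0 when there are no deletion
#'     reads. Clonal somatic deletions are unimodal (bias near 1) while PCR
#'     stutter is dispersed.}
#' }
#' The sample-specific reference length is the modal observed length when it
#' lies within one unit of the panel reference (tolerating germline length
#' polymorphism), otherwise the panel reference length. Modal ties are broken
#' towards the length closest to the panel reference, then towards the longer
#' allele.
#'
#' @param spectra a \linkS4class{SampleSpectra}.
#' @param panel a \linkS4class{MarkerPanel}.
#' @return data.frame with columns \code{marker}, \code{del_freq},
#'   \code{allelic_bias}, \code{depth}, \code{ref_used}; one row per marker
#'   with depth > 0 (possibly zero rows).
#' @export
computeFeatures <- function(spectra, panel) {
    stopifnot(is(spectra, "SampleSpectra"), is(panel, "MarkerPanel"))
    m <- panel@markers
    rows <- lapply(seq_len(nrow(m)), function(i) {
        v <- spectra@counts[[m$name[i]]]
        if (is.null(v) || !length(v) || sum(v) == 0) return(NULL)
        lens <- as.integer(names(v))
        depth <- sum(v)
        cand <- lens[v == max(v)]
        cand <- cand[order(abs(cand - m$ref_length[i]), -cand)]
        modal <- cand[1L]
        ref <- if (abs(modal - m$ref_length[i]) <= 1L) modal else m$ref_length[i]
        del <- lens < ref
        del_freq <- sum(v[del]) / depth
        bias <- if (any(del)) max(v[del]) / sum(v[del]) else 0
        data.frame(marker = m$name[i], del_freq = del_freq,
                   allelic_bias = bias, depth = depth, ref_used = ref,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(marker = character(0), del_freq = numeric(0),
                          allelic_bias = numeric(0), depth = numeric(0),
                          ref_used = integer(0))
    out
}

# Method-of-moments Beta fit on proportions already shrunk into (0,1).
# Falls back to the flat Beta(1,1) when the moment solution is invalid.
.fitBetaMoments <- function(x) {
    m <- mean(x)
    v <- stats::var(x)
    if (!is.finite(v) || v <= 0 || v >= m * (1 - m))
        return(c(alpha = 1, beta = 1))
    common <- m * (1 - m) / v - 1
    c(alpha = m * common, beta = (1 - m) * common)
}

#' Train the naive Bayes MSI model
#'
#' Fits, per marker, per class (MSS, MSI-H) and per feature (deletion
#' frequency, allelic bias), a Beta distribution by the method of moments on
#' feature values shrunk into the open unit interval by
#' \code{x -> (x*n + 0.5)/(n + 1)} with \code{n} the class sample count.
#' When the moment solution is invalid (sample variance at least
#' \code{mean*(1-mean)}, or zero) the flat Beta(1,1) is used for that cell.
#'
#' @param spectra_list list of \linkS4class{SampleSpectra}, the training
#'   cohort.
#' @param labels character vector ("MSS" or "MSI-H"), one label per sample.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param prior_log_odds prior log odds added to every score (default 0).
#' @return a validated \linkS4class{MsiModel} covering every panel marker.
#' @seealso [msiScore()], [saveModel()]
#' @export
fitMsiModel <- function(spectra_list, labels, panel, prior_log_odds = 0) {
    stopifnot(is(panel, "MarkerPanel"))
    labels <- as.character(labels)
    if (length(spectra_list) != length(labels))
        stopValidation("one label per training sample required")
    if (!all(labels %in% c("MSS", "MSI-H")))
        stopValidation("labels must be 'MSS' or 'MSI-H'")
    nPer <- table(factor(labels, levels = c("MSS", "MSI-H")))
    if (any(nPer < 5))
        stopValidation("need at least 5 training samples per class; got MSS=",
                       nPer[["MSS"]], ", MSI-H=", nPer[["MSI-H"]])
    feats <- lapply(spectra_list, computeFeatures, panel = panel)

    params <- list()
    for (mk in markerNames(panel)) {
        for (cls in c("MSS", "MSI-H")) {
            idx <- which(labels == cls)
            vals <- do.call(rbind, lapply(feats[idx], function(f)
                f[f$marker == mk, c("del_freq", "allelic_bias")]))
            if (is.null(vals) || nrow(vals) == 0L) {
                anyAtAll <- any(vapply(feats, function(f)
                    mk %in% f$marker, logical(1)))
                stopValidation("marker '", mk, "' has no observations in ",
                               if (anyAtAll) paste0("class ", cls)
                               else "any training sample")
            }
            n <- as.numeric(nPer[[cls]])
            for (ft in c("del_freq", "allelic_bias")) {
                ab <- .fitBetaMoments(shrinkProportion(vals[[ft]], n))
                params[[length(params) + 1L]] <- data.frame(
                    marker = mk, class = cls, feature = ft,
                    alpha = ab[["alpha"]], beta = ab[["beta"]],
                    stringsAsFactors = FALSE)
            }
        }
    }
    new("MsiModel", params = do.call(rbind, params),
        prior_log_odds = prior_log_odds,
        n_train = c(MSS = as.numeric(nPer[["MSS"]]),
                    `MSI-H` = as.numeric(nPer[["MSI-H"]])),
        version = "seqmsi-model-1")
}

#' Construct an MSI model from explicit parameters
#'
#' Mainly useful for toy models in examples and tests; [fitMsiModel()] is the
#' normal route.
#'
#' @param params data.frame with columns \code{marker}, \code{class},
#'   \code{feature}, \code{alpha}, \code{beta}.
#' @param prior_log_odds prior log odds (default 0).
#' @param n_train named numeric, per-class training sizes (used as the
#'   shrinkage constants at scoring time).
#' @return a validated \linkS4class{MsiModel}.
#' @export
MsiModel <- function(params, prior_log_odds = 0,
                     n_train = c(MSS = 1e6, `MSI-H` = 1e6)) {
    new("MsiModel", params = params, prior_log_odds = prior_log_odds,
        n_train = n_train, version = "seqmsi-model-1")
}

#' @describeIn MsiModel markers covered by the model.
#' @param x a \linkS4class{MsiModel}.
#' @export
setMethod("markerNames", "MsiModel", function(x) unique(x@params$marker))

setMethod("show", "MsiModel", function(object) {
    cat("MsiModel (", object@version, "): ",
        length(unique(object@params$marker)), " markers, trained on MSS=",
        object@n_train[["MSS"]], " / MSI-H=", object@n_train[["MSI-H"]],
        ", prior log odds ", object@prior_log_odds, "\n", sep = "")
})

# Sum of log Beta densities (floored at 1e-300) for one class.
.classLogLik <- function(features, params, cls, n) {
    total <- 0
    for (i in seq_len(nrow(features))) {
        mk <- features$marker[i]
        for (ft in c("del_freq", "allelic_bias")) {
            row <- params[params$marker == mk & params$class == cls &
                          params$feature == ft, ]
            x <- shrinkProportion(features[[ft]][i], n)
            d <- max(stats::dbeta(x, row$alpha, row$beta), 1e-300)
            total <- total + log(d)
        }
    }
    total
}

#' Naive Bayes MSI score
#'
#' The MSI score is the natural-log Bayes factor of MSI-H over MSS under the
#' naive Bayes model: the prior log odds plus, summed over the sample's
#' observed markers, the log ratio of class-conditional Beta densities for
#' the deletion frequency and for the allelic bias. Markers and features are
#' treated as independent; markers with no reads contribute nothing (missing
#' evidence is marginalised out). Each class's densities are evaluated at the
#' feature value shrunk with that class's training sample count, matching how
#' the conditionals were fitted; densities are floored at 1e-300 before
#' taking logs so the score is always finite.
#'
#' A positive score favours MSI-H; a negative score favours MSS.
#'
#' @param features data.frame from [computeFeatures()].
#' @param model a \linkS4class{MsiModel} covering every feature marker.
#' @return a single numeric score.
#' @export
msiScore <- function(features, model) {
    stopifnot(is(model, "MsiModel"))
    unknown <- setdiff(features$marker, markerNames(model))
    if (length(unknown))
        stopValidation("model does not cover marker(s): ",
                       paste(unknown, collapse = ", "))
    if (nrow(features) == 0L) return(model@prior_log_odds)
    model@prior_log_odds +
        .classLogLik(features, model@params, "MSI-H",
                     model@n_train[["MSI-H"]]) -
        .classLogLik(features, model@params, "MSS", model@n_train[["MSS"]])
}

#' Classify a sample from its MSI score
#'
#' Decision rule: a QC failure is called "fail" regardless of score. A score
#' outside the confirmation band (|score| >= band) is called by sign: MSI-H
#' for positive, MSS for negative. A score inside the band requires a repeat
#' assay: if a repeat score with the same sign is supplied the call follows
#' that sign; a conflicting (opposite-signed or zero) repeat score yields
#' "uncertain" with the reported score set to 0. With no repeat score the
#' provisional call follows the sign (score exactly 0 is "uncertain") and
#' \code{needs_repeat} is flagged.
#'
#' @param score the sample MSI score.
#' @param qc logical QC status from [qcPass()].
#' @param band half-width of the confirmation band on the log-Bayes-factor
#'   scale (default 5).
#' @param repeat_score optional score from a repeat assay.
#' @param sample_id identifier stored in the result.
#' @return a \linkS4class{MsiResult}.
#' @export
classifyMsi <- function(score, qc, band = 5.0, repeat_score = NULL,
                        sample_id = "sample") {
    res <- function(call, rep_score = score, needs = FALSE)
        new("MsiResult", sample_id = as.character(sample_id),
            msi_score = rep_score, qc = qc, call = call,
            needs_repeat = needs,
            repeat_scores = if (is.null(repeat_score)) numeric(0)
                            else repeat_score)
    if (!qc) return(res("fail"))
    bySign <- function(s) if (s > 0) "MSI-H" else "MSS"
    if (abs(score) >= band) return(res(bySign(score)))
    if (!is.null(repeat_score)) {
        if (sign(repeat_score) == sign(score) && score != 0)
            return(res(bySign(score), needs = FALSE))
        return(res("uncertain", rep_score = 0))
    }
    if (score == 0) return(res("uncertain", rep_score = 0, needs = TRUE))
    res(bySign(score), needs = TRUE)
}

#' @describeIn MsiResult the MSI call.
#' @param x a \linkS4class{MsiResult}.
#' @export
setMethod("msiCall", "MsiResult", function(x) x@call)

#' @describeIn MsiResult sample identifier.
#' @export
setMethod("sampleId", "MsiResult", function(x) x@sample_id)

#' Reported MSI score of a result
#'
#' @param result a \linkS4class{MsiResult}.
#' @return numeric score (0 for uncertain calls).
#' @export
resultScore <- function(result) result@msi_score

setMethod("show", "MsiResult", function(object) {
    cat("MsiResult '", object@sample_id, "': call=", object@call,
        ", score=", format(object@msi_score, digits = 4),
        ", qc=", ifelse(object@qc, "pass", "fail"),
        if (object@needs_repeat) " (needs repeat)" else "", "\n", sep = "")
})

#' Score and classify one sample end to end
#'
#' Convenience wrapper: depth QC, feature computation, scoring and
#' classification in one call.
#'
#' @param spectra a \linkS4class{SampleSpectra}.
#' @param model a \linkS4class{MsiModel}.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param band confirmation band half-width (default 5).
#' @param min_median_depth QC threshold (default 100).
#' @param repeat_score optional repeat-assay score.
#' @return a \linkS4class{MsiResult}.
#' @export
scoreSample <- function(spectra, model, panel, band = 5.0,
                        min_median_depth = 100, repeat_score = NULL) {
    qc <- qcPass(spectra, min_median_depth)
    s <- msiScore(computeFeatures(spectra, panel), model)
    classifyMsi(s, qc, band = band, repeat_score = repeat_score,
                sample_id = sampleId(spectra))
}

#' Score a cohort of samples
#'
#' @param spectra_list list of \linkS4class{SampleSpectra}.
#' @param model a \linkS4class{MsiModel}.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param band,min_median_depth see [scoreSample()].
#' @return data.frame with columns \code{sample_id}, \code{msi_score},
#'   \code{qc}, \code{call}, \code{needs_repeat}.
#' @export
scoreCohort <- function(spectra_list, model, panel, band = 5.0,
                        min_median_depth = 100) {
    rows <- lapply(spectra_list, function(s) {
        r <- scoreSample(s, model, panel, band, min_median_depth)
        data.frame(sample_id = r@sample_id, msi_score = r@msi_score,
                   qc = r@qc, call = r@call, needs_repeat = r@needs_repeat,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Save / load an MSI model as JSON
#'
#' The JSON schema is versioned; parameters round-trip losslessly (full
#' double precision).
#'
#' @param model a \linkS4class{MsiModel}.
#' @param path path to the model JSON file.
#' @return \code{loadModel}: a validated \linkS4class{MsiModel}.
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "MsiModel"))
    obj <- list(schema = "seqmsi-model", version = model@version,
                prior_log_odds = model@prior_log_odds,
                n_train = as.list(model@n_train),
                params = model@params)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    if (!file.exists(path))
        stopValidation("model file not found: ", path)
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) stopValidation(
                        "unreadable model JSON '", path, "': ",
                        conditionMessage(e)))
    if (!identical(obj$schema, "seqmsi-model"))
        stopValidation("not a seqmsi model file (schema mismatch)")
    if (!identical(obj$version, "seqmsi-model-1"))
        stopValidation("unsupported model version: ", obj$version)
    tryCatch(
        new("MsiModel", params = as.data.frame(obj$params),
            prior_log_odds = obj$prior_log_odds,
            n_train = unlist(obj$n_train), version = obj$version),
        error = function(e) stopValidation("invalid model contents: ",
                                           conditionMessage(e)))
}
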