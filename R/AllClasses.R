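#' @import methods
NULL

.DNA_RE <- "^[ACGT]+$"

#' MarkerPanel: a microsatellite marker panel
#'
#' Holds the ordered set of microsatellite markers that the extraction,
#' simulation and scoring layers operate on. Each marker is a mononucleotide
#' or short-unit repeat locus described by its repeat unit, the number of
#' repeat units in the reference allele, and the unique flanking sequences
#' used to anchor reads to the locus.
#'
#' Validity requires: marker names unique; \code{ref_length >= 5}; repeat
#' unit and flanks are ACGT strings with flanks at least 8 nt; and neither
#' flank carries a run of three or more repeat units at the junction end
#' (the 3' end of \code{flank5}, the 5' end of \code{flank3}), which
#' guarantees that the repeat tract is unambiguously delimited.
#'
#' @slot markers data.frame with columns \code{name}, \code{repeat_unit},
#'   \code{ref_length}, \code{flank5}, \code{flank3}.
#' @slot version free-text panel version label.
#'
#' @seealso [loadPanel()], [defaultPanel()], [markerNames()]
#' @export
setClass("MarkerPanel",
    representation(markers = "data.frame", version = "character"))

setValidity("MarkerPanel", function(object) {
    m <- object@markers
    need <- c("name", "repeat_unit", "ref_length", "flank5", "flank3")
    if (!all(need %in% names(m)))
        return(paste("markers must have columns:", paste(need, collapse = ", ")))
    if (nrow(m) == 0L)
        return("panel has no markers")
    if (anyDuplicated(m$name))
        return(paste0("duplicate marker name(s): ",
                      paste(unique(m$name[duplicated(m$name)]), collapse = ", ")))
    if (!all(grepl(.DNA_RE, m$repeat_unit)))
        return("repeat_unit must be a non-empty ACGT string")
    if (any(m$ref_length < 5) || any(m$ref_length != round(m$ref_length)))
        return("ref_length must be an integer >= 5 (repeat units)")
    if (!all(grepl(.DNA_RE, m$flank5)) || !all(grepl(.DNA_RE, m$flank3)))
        return("flanks must be ACGT strings")
    if (any(nchar(m$flank5) < 8) || any(nchar(m$flank3) < 8))
        return("flanks must be at least 8 nt")
    run3 <- strrep(m$repeat_unit, 3L)
    amb5 <- substring(m$flank5, nchar(m$flank5) - nchar(run3) + 1L) == run3
    amb3 <- substring(m$flank3, 1L, nchar(run3)) == run3
    if (any(amb5 | amb3))
        return(paste0("ambiguous flank/repeat junction for marker(s): ",
                      paste(m$name[amb5 | amb3], collapse = ", "),
                      " (flank carries a >= 3-unit run of the repeat unit at the junction)"))
    TRUE
})

#' SampleSpectra: per-marker repeat-length spectra for one sample
#'
#' The per-sample result of assigning reads to panel markers: for each
#' marker, a histogram of observed repeat lengths (in repeat units) with
#' the read count at each length. Reads that match no marker are tallied
#' in \code{unassigned} so that read counts are conserved.
#'
#' @slot sample_id sample identifier.
#' @slot counts named list, one element per panel marker; each element is a
#'   named integer vector mapping repeat length (as the name) to read count.
#'   An empty vector means depth 0 for that marker.
#' @slot unassigned integer count of input reads assigned to no marker.
#'
#' @seealso [extractSpectra()], [spectraDepths()], [medianDepth()], [qcPass()]
#' @export
setClass("SampleSpectra",
    representation(sample_id = "character", counts = "list",
                   unassigned = "integer"))

setValidity("SampleSpectra", function(object) {
    if (length(object@sample_id) != 1L || is.na(object@sample_id))
        return("sample_id must be a single non-NA string")
    for (nm in names(object@counts)) {
        v <- object@counts[[nm]]
        if (length(v) == 0L) next
        if (is.null(names(v)) || anyNA(suppressWarnings(as.integer(names(v)))))
            return(paste0("marker '", nm, "': counts must be named by integer repeat length"))
        if (any(v < 0))
            return(paste0("marker '", nm, "': negative read count"))
        if (any(as.integer(names(v)) < 0))
            return(paste0("marker '", nm, "': negative repeat length"))
    }
    if (length(object@unassigned) != 1L || object@unassigned < 0L)
        return("unassigned must be a single non-negative integer")
    TRUE
})

#' MsiModel: trained naive Bayes MSI classifier
#'
#' Class-conditional Beta distributions, per marker and per class (MSS,
#' MSI-H), for the two per-marker features: deletion frequency and allelic
#' bias. A sample's MSI score is the naive Bayes log-likelihood ratio
#' (natural log) of MSI-H over MSS summed across markers and features, plus
#' \code{prior_log_odds}.
#'
#' @slot params data.frame with columns \code{marker}, \code{class} (one of
#'   "MSS", "MSI-H"), \code{feature} (one of "del_freq", "allelic_bias"),
#'   \code{alpha}, \code{beta}.
#' @slot prior_log_odds prior log odds added to every score (default 0).
#' @slot n_train named numeric, training cohort size per class; also the
#'   shrinkage constant used when evaluating that class's densities.
#' @slot version model schema version string.
#'
#' @seealso [fitMsiModel()], [msiScore()], [saveModel()], [loadModel()]
#' @export
setClass("MsiModel",
    representation(params = "data.frame", prior_log_odds = "numeric",
                   n_train = "numeric", version = "character"))

setValidity("MsiModel", function(object) {
    p <- object@params
    need <- c("marker", "class", "feature", "alpha", "beta")
    if (!all(need %in% names(p)))
        return(paste("params must have columns:", paste(need, collapse = ", ")))
    if (!all(p$class %in% c("MSS", "MSI-H")))
        return("class must be 'MSS' or 'MSI-H'")
    if (!all(p$feature %in% c("del_freq", "allelic_bias")))
        return("feature must be 'del_freq' or 'allelic_bias'")
    if (any(p$alpha <= 0) || any(p$beta <= 0))
        return("all Beta parameters must be > 0")
    have <- with(p, table(marker))
    if (any(have != 4L))
        return("each marker needs 4 parameter rows (2 classes x 2 features)")
    if (!all(c("MSS", "MSI-H") %in% names(object@n_train)))
        return("n_train must be named with both classes")
    if (any(object@n_train < 1))
        return("n_train must be >= 1 per class")
    TRUE
})

#' MsiResult: sample-level MSI classification
#'
#' @slot sample_id sample identifier.
#' @slot msi_score the reported MSI score (0 for uncertain calls).
#' @slot qc logical, TRUE if the sample passed depth QC.
#' @slot call one of "MSI-H", "MSS", "uncertain", "fail".
#' @slot needs_repeat logical, TRUE when the initial score fell inside the
#'   confirmation band and no confirming repeat score was available.
#' @slot repeat_scores numeric vector of repeat-assay scores used (may be
#'   empty).
#'
#' @seealso [classifyMsi()], [scoreSample()]
#' @export
setClass("MsiResult",
    representation(sample_id = "character", msi_score = "numeric",
                   qc = "logical", call = "character",
                   needs_repeat = "logical", repeat_scores = "numeric"))

setValidity("MsiResult", function(object) {
    if (!object@call %in% c("MSI-H", "MSS", "uncertain", "fail"))
        return("call must be one of MSI-H, MSS, uncertain, fail")
    if (object@call == "MSI-H" && !(object@msi_score > 0))
        return("MSI-H call requires reported score > 0")
    if (object@call == "MSS" && !(object@msi_score < 0))
        return("MSS call requires reported score < 0")
    if (object@call == "uncertain" && object@msi_score != 0)
        return("uncertain call must report score 0")
    TRUE
})
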