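#' Simulation configuration
#'
#' Parameters of the synthetic amplicon cohort generator. Defaults emulate
#' the assay conditions the scoring layer is designed for: ~2000x per-marker
#' read depth, deletion-biased PCR stutter on mononucleotide repeats, a
#' clonal somatic deletion allele present in roughly a third of reads in
#' MSI-high tumours, and an attenuated-instability subclass mimicking
#' isolated MSH6 deficiency (same deletion allele at a reduced clonal
#' fraction).
#'
#' @param seed integer RNG seed; a fixed seed makes every output
#'   reproducible.
#' @param n_mss,n_msih,n_msh6like class sample counts (defaults 50/30/10).
#' @param depth_mean mean per-marker read depth; per-sample, per-marker
#'   depths are Poisson(depth_mean) (default 2000).
#' @param stutter_rate per-unit polymerase slippage probability per read
#'   (default 0.002); a template of L units loses at least one unit with
#'   probability 1 - (1 - stutter_rate)^L.
#' @param somatic_fraction clonal fraction of the somatic deletion allele in
#'   MSI-H samples (default 0.35).
#' @param msh6_fraction_multiplier multiplier in (0,1] applied to
#'   \code{somatic_fraction} for the MSH6-like subclass (default 0.35).
#' @param somatic_del_units size of the somatic deletion, in repeat units
#'   (default 3).
#' @param marker_dropout_prob probability that a marker yields no reads in a
#'   sample (default 0); exercises the depth-QC path.
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, n_mss = 50L, n_msih = 30L,
                             n_msh6like = 10L, depth_mean = 2000,
                             stutter_rate = 0.002, somatic_fraction = 0.35,
                             msh6_fraction_multiplier = 0.35,
                             somatic_del_units = 3L,
                             marker_dropout_prob = 0) {
    cfg <- list(seed = as.integer(seed), n_mss = as.integer(n_mss),
                n_msih = as.integer(n_msih),
                n_msh6like = as.integer(n_msh6like),
                depth_mean = depth_mean, stutter_rate = stutter_rate,
                somatic_fraction = somatic_fraction,
                msh6_fraction_multiplier = msh6_fraction_multiplier,
                somatic_del_units = as.integer(somatic_del_units),
                marker_dropout_prob = marker_dropout_prob)
    if (any(c(cfg$n_mss, cfg$n_msih, cfg$n_msh6like) < 0))
        stopValidation("class counts must be non-negative")
    if (cfg$depth_mean <= 0)
        stopValidation("depth_mean must be > 0")
    probs <- c(cfg$stutter_rate, cfg$somatic_fraction,
               cfg$marker_dropout_prob)
    if (any(probs < 0 | probs > 1))
        stopValidation("stutter_rate, somatic_fraction and marker_dropout_prob must be in [0,1]")
    if (cfg$msh6_fraction_multiplier <= 0 || cfg$msh6_fraction_multiplier > 1)
        stopValidation("msh6_fraction_multiplier must be in (0,1]")
    if (cfg$somatic_del_units < 1)
        stopValidation("somatic_del_units must be >= 1")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Simulate one marker's allele-length spectrum
#'
#' Each read draws its template allele: the reference length with probability
#' \code{1 - somatic_fraction}, or the somatic deletion allele
#' (\code{ref_length - somatic_del_units}) with probability
#' \code{somatic_fraction}. PCR stutter then removes \code{D} repeat units:
#' \code{D = 0} with probability \code{(1 - stutter_rate)^L} for a template of
#' \code{L} units; otherwise \code{D} is 1 plus a Geometric(0.5) draw,
#' truncated at the template length. Stutter is deletion-biased (no
#' insertions), the dominant error mode for mononucleotide repeats.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param ref_length reference allele length, repeat units.
#' @param depth number of reads to draw (> 0).
#' @param stutter_rate per-unit slippage probability.
#' @param somatic_fraction clonal fraction of the deletion allele.
#' @param somatic_del_units somatic deletion size, units.
#' @return named integer vector of counts by observed repeat length; counts
#'   sum to \code{depth}.
#' @export
simulateSpectrum <- function(ref_length, depth, stutter_rate = 0.002,
                             somatic_fraction = 0, somatic_del_units = 3L) {
    if (depth <= 0) stopValidation("depth must be > 0")
    if (stutter_rate < 0 || stutter_rate > 1 ||
        somatic_fraction < 0 || somatic_fraction > 1)
        stopValidation("stutter_rate and somatic_fraction must be in [0,1]")
    somatic <- stats::runif(depth) < somatic_fraction
    templ <- ref_length - somatic_del_units * somatic
    templ <- pmax(templ, 0L)
    p_del <- 1 - (1 - stutter_rate)^templ
    slipped <- stats::runif(depth) < p_del
    d <- integer(depth)
    if (any(slipped))
        d[slipped] <- pmin(1L + stats::rgeom(sum(slipped), 0.5),
                           templ[slipped])
    obs <- templ - d
    tab <- table(obs)
    setNames(as.integer(tab), names(tab))
}

# Reference-cohort IHC staining patterns among MMR-deficient tumours that are
# not isolated-MSH6: the empirical pattern weights used when assigning IHC
# annotations to simulated MSI-H samples.
.MSIH_IHC_PATTERNS <- list(
    list(w = 1,  mlh1 = "loss",      pms2 = "loss", msh2 = "loss",     msh6 = "loss"),
    list(w = 1,  mlh1 = "retained",  pms2 = "loss", msh2 = "loss",     msh6 = "loss"),
    list(w = 27, mlh1 = "retained",  pms2 = "retained", msh2 = "loss", msh6 = "loss"),
    list(w = 6,  mlh1 = "loss",      pms2 = "loss", msh2 = "retained", msh6 = "retained"),
    list(w = 9,  mlh1 = "equivocal", pms2 = "loss", msh2 = "retained", msh6 = "retained"),
    list(w = 1,  mlh1 = "retained",  pms2 = "loss", msh2 = "retained", msh6 = "retained"))

.drawIhcPattern <- function(true_class) {
    if (true_class == "MSS")
        return(c(mlh1 = "retained", pms2 = "retained", msh2 = "retained",
                 msh6 = "retained"))
    if (true_class == "MSH6-like")
        return(c(mlh1 = "retained", pms2 = "retained", msh2 = "retained",
                 msh6 = "loss"))
    w <- vapply(.MSIH_IHC_PATTERNS, `[[`, numeric(1), "w")
    p <- .MSIH_IHC_PATTERNS[[sample.int(length(w), 1L, prob = w)]]
    c(mlh1 = p$mlh1, pms2 = p$pms2, msh2 = p$msh2, msh6 = p$msh6)
}

#' Simulate a labelled cohort
#'
#' Generates per-sample allele spectra for every panel marker plus a truth
#' table. MSS samples carry no somatic deletion allele; MSI-H samples carry
#' it at \code{somatic_fraction} on every marker; MSH6-like samples at
#' \code{somatic_fraction * msh6_fraction_multiplier}, modelling the
#' attenuated instability of isolated MSH6 deficiency. Per-sample, per-marker
#' depths are Poisson. IHC-style annotations consistent with the true class
#' are attached: MSS samples retain all four proteins, MSH6-like samples show
#' isolated MSH6 loss, and MSI-H samples draw a staining pattern from the
#' empirical distribution of MMR-deficient patterns in the reference cohort
#' (MSH2/MSH6 co-loss the majority, MLH1/PMS2-family patterns next).
#'
#' Deterministic given \code{config$seed}.
#'
#' @param config a [simulationConfig()].
#' @param panel a \linkS4class{MarkerPanel} (default [defaultPanel()]).
#' @return list with \code{spectra} (named list of
#'   \linkS4class{SampleSpectra}) and \code{truth} (data.frame
#'   \code{sample_id, true_class, mlh1, pms2, msh2, msh6}).
#' @export
simulateCohort <- function(config, panel = defaultPanel()) {
    stopifnot(inherits(config, "SimulationConfig"), is(panel, "MarkerPanel"))
    nTot <- config$n_mss + config$n_msih + config$n_msh6like
    if (nTot == 0L)
        stopValidation("at least one sample required across classes")
    set.seed(config$seed)
    classes <- rep(c("MSS", "MSI-H", "MSH6-like"),
                   c(config$n_mss, config$n_msih, config$n_msh6like))
    ids <- sprintf("S%03d", seq_len(nTot))
    m <- panel@markers
    fracFor <- c(MSS = 0, `MSI-H` = config$somatic_fraction,
                 `MSH6-like` = config$somatic_fraction *
                               config$msh6_fraction_multiplier)
    spectra <- vector("list", nTot)
    truth <- vector("list", nTot)
    for (s in seq_len(nTot)) {
        counts <- setNames(vector("list", nrow(m)), m$name)
        for (i in seq_len(nrow(m))) {
            drop <- config$marker_dropout_prob > 0 &&
                stats::runif(1) < config$marker_dropout_prob
            depth <- if (drop) 0L else stats::rpois(1L, config$depth_mean)
            counts[[i]] <- if (depth == 0L) integer(0) else
                simulateSpectrum(m$ref_length[i], depth,
                                 config$stutter_rate,
                                 fracFor[[classes[s]]],
                                 config$somatic_del_units)
        }
        spectra[[s]] <- SampleSpectra(ids[s], counts)
        pat <- .drawIhcPattern(classes[s])
        truth[[s]] <- data.frame(sample_id = ids[s], true_class = classes[s],
                                 mlh1 = pat[["mlh1"]], pms2 = pat[["pms2"]],
                                 msh2 = pat[["msh2"]], msh6 = pat[["msh6"]],
                                 stringsAsFactors = FALSE)
    }
    names(spectra) <- ids
    list(spectra = spectra, truth = do.call(rbind, truth))
}

#' Emit reads for sample spectra
#'
#' One read per spectrum count: \code{flank5 + repeat_unit x length + flank3},
#' constant base quality. [extractSpectra()] on the output reproduces the
#' input counts exactly.
#'
#' @param spectra a \linkS4class{SampleSpectra}.
#' @param panel the \linkS4class{MarkerPanel} the spectra refer to.
#' @param path optional FASTQ output path; when NULL the reads are returned.
#' @return invisibly \code{path} when writing, otherwise a
#'   \code{Biostrings::DNAStringSet} of reads.
#' @export
emitReads <- function(spectra, panel, path = NULL) {
    stopifnot(is(spectra, "SampleSpectra"), is(panel, "MarkerPanel"))
    m <- panel@markers
    reads <- character(0)
    for (i in seq_len(nrow(m))) {
        v <- spectra@counts[[m$name[i]]]
        if (is.null(v) || !length(v)) next
        lens <- rep(as.integer(names(v)), v)
        reads <- c(reads, paste0(m$flank5[i],
                                 strrep(m$repeat_unit[i], lens),
                                 m$flank3[i]))
    }
    dss <- Biostrings::DNAStringSet(reads)
    if (length(dss))
        names(dss) <- sprintf("%s_read%06d", spectra@sample_id,
                              seq_along(dss))
    if (is.null(path)) return(dss)
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = quals)
    invisible(path)
}

#' Write a cohort truth table as CSV
#'
#' Columns: \code{sample_id, true_class, mlh1, pms2, msh2, msh6}.
#'
#' @param truth the truth data.frame from [simulateCohort()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTruthCsv <- function(truth, path) {
    utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
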