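#' Construct per-sample allele spectra
#'
#' @param sample_id sample identifier.
#' @param counts named list with one element per panel marker: a named
#'   integer vector mapping repeat length (units) to read count. Elements may
#'   be empty (depth 0).
#' @param unassigned number of reads assigned to no marker.
#' @return a validated \linkS4class{SampleSpectra}.
#' @export
SampleSpectra <- function(sample_id, counts, unassigned = 0L) {
    counts <- lapply(counts, function(v) {
        if (length(v) == 0L) return(setNames(integer(0), character(0)))
        v <- v[order(as.integer(names(v)))]
        storage.mode(v) <- "integer"
        v
    })
    new("SampleSpectra", sample_id = as.character(sample_id),
        counts = counts, unassigned = as.integer(unassigned))
}

#' @describeIn SampleSpectra sample identifier.
#' @param x a \linkS4class{SampleSpectra}.
#' @export
setMethod("sampleId", "SampleSpectra", function(x) x@sample_id)

#' @describeIn SampleSpectra marker names covered by the spectra.
#' @export
setMethod("markerNames", "SampleSpectra", function(x) names(x@counts))

#' @describeIn SampleSpectra total assigned reads per marker.
#' @export
setMethod("spectraDepths", "SampleSpectra", function(x)
    vapply(x@counts, function(v) sum(as.numeric(v)), numeric(1)))

#' @describeIn SampleSpectra lower-median of per-marker depths.
#' @export
setMethod("medianDepth", "SampleSpectra", function(x)
    lowerMedian(spectraDepths(x)))

setMethod("show", "SampleSpectra", function(object) {
    d <- spectraDepths(object)
    cat("SampleSpectra '", object@sample_id, "': ", length(d), " markers, ",
        "median depth ", lowerMedian(d), " (lower median), ",
        object@unassigned, " unassigned reads\n", sep = "")
})

#' Repeat-length counts for one marker
#'
#' @param spectra a \linkS4class{SampleSpectra}.
#' @param marker marker name.
#' @return named integer vector (names = repeat length in units).
#' @export
spectrumCounts <- function(spectra, marker) {
    stopifnot(is(spectra, "SampleSpectra"))
    if (!marker %in% names(spectra@counts))
        stopValidation("unknown marker: ", marker)
    spectra@counts[[marker]]
}

#' Depth-based sample quality control
#'
#' A sample passes QC when its median per-marker read depth (lower-median
#' convention) is at least \code{min_median_depth}.
#'
#' @param spectra a \linkS4class{SampleSpectra}.
#' @param min_median_depth minimum median depth (default 100).
#' @return logical.
#' @export
qcPass <- function(spectra, min_median_depth = 100) {
    stopifnot(is(spectra, "SampleSpectra"))
    medianDepth(spectra) >= min_median_depth
}

# Count complete leading copies of `unit` in each string of `x`.
.leadingUnits <- function(x, unit) {
    m <- regexpr(sprintf("^(?:%s)*", unit), x, perl = TRUE)
    attr(m, "match.length") %/% nchar(unit)
}

#' Extract per-marker allele spectra from reads
#'
#' Assigns each read to at most one marker by exact flank anchoring: the
#' first marker (in panel order) whose 5' flank and, downstream of it, 3'
#' flank both occur in the read or in its reverse complement. The repeat
#' length recorded for the read is the number of complete repeat-unit copies
#' immediately following the 5' flank; partial trailing units are not
#' counted. Reads matching no marker are tallied as unassigned.
#'
#' @param reads a FASTQ file path, a \code{Biostrings::DNAStringSet}, or a
#'   character vector of read sequences.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param sample_id sample identifier for the result.
#' @return a \linkS4class{SampleSpectra} covering every panel marker.
#' @examples
#' p <- defaultPanel()
#' m <- panelMarkers(p)[1, ]
#' rd <- paste0(m$flank5, strrep(m$repeat_unit, 10), m$flank3)
#' spectrumCounts(extractSpectra(rd, p), m$name)  # one read at length 10
#' @export
extractSpectra <- function(reads, panel, sample_id = "sample") {
    stopifnot(is(panel, "MarkerPanel"))
    if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
        reads <- tryCatch(
            Biostrings::readDNAStringSet(reads, format = "fastq"),
            error = function(e) stopValidation(
                "unreadable FASTQ '", reads, "': ", conditionMessage(e)))
    }
    if (is(reads, "DNAStringSet")) {
        fwd <- as.character(reads)
        rev <- as.character(Biostrings::reverseComplement(reads))
    } else {
        fwd <- toupper(as.character(reads))
        rev <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(fwd)))
    }
    names(fwd) <- names(rev) <- NULL

    m <- panel@markers
    counts <- setNames(vector("list", nrow(m)), m$name)
    open <- seq_along(fwd)                      # reads not yet assigned
    for (i in seq_len(nrow(m))) {
        lens <- integer(0)
        hit <- logical(length(open))
        for (ori in list(fwd, rev)) {
            s <- ori[open]
            i5 <- regexpr(m$flank5[i], s, fixed = TRUE)
            rest <- ifelse(i5 > 0L,
                           substring(s, i5 + nchar(m$flank5[i])), "")
            i3 <- regexpr(m$flank3[i], rest, fixed = TRUE)
            ok <- i5 > 0L & i3 > 0L & !hit
            if (any(ok)) {
                between <- substring(rest[ok], 1L, i3[ok] - 1L)
                lens <- c(lens, .leadingUnits(between, m$repeat_unit[i]))
                hit <- hit | ok
            }
        }
        if (length(lens)) {
            tab <- table(lens)
            counts[[i]] <- setNames(as.integer(tab), names(tab))
            open <- open[!hit]
        } else {
            counts[[i]] <- integer(0)
        }
        if (!length(open)) {
            counts[seq_len(nrow(m))[-seq_len(i)]] <-
                list(setNames(integer(0), character(0)))
            break
        }
    }
    counts[vapply(counts, is.null, logical(1))] <-
        list(setNames(integer(0), character(0)))
    SampleSpectra(sample_id, counts, unassigned = length(open))
}

#' Read/write sample spectra as TSV
#'
#' Long format with columns \code{sample_id, marker, length, count}
#' (tab-separated). Depth-0 markers have no rows; they are restored from
#' \code{panel} on read, so the round trip is lossless.
#'
#' @param path path to the spectra TSV.
#' @param panel a \linkS4class{MarkerPanel}; defines the marker universe so
#'   depth-0 markers round-trip.
#' @return \code{readSpectraTsv}: a named list of
#'   \linkS4class{SampleSpectra}, one per sample id in the file.
#' @export
readSpectraTsv <- function(path, panel) {
    stopifnot(is(panel, "MarkerPanel"))
    if (!file.exists(path))
        stopValidation("spectra file not found: ", path)
    df <- tryCatch(
        utils::read.delim(path, stringsAsFactors = FALSE),
        error = function(e) stopValidation("unreadable spectra TSV: ",
                                           conditionMessage(e)))
    need <- c("sample_id", "marker", "length", "count")
    if (!all(need %in% names(df)))
        stopValidation("spectra TSV needs columns: ",
                       paste(need, collapse = ", "))
    if (any(df$count < 0))
        stopValidation("negative read count in spectra TSV")
    if (any(df$length < 0))
        stopValidation("negative repeat length in spectra TSV")
    unknown <- setdiff(unique(df$marker), markerNames(panel))
    if (length(unknown))
        stopValidation("spectra TSV references markers not in panel: ",
                       paste(unknown, collapse = ", "))
    lapply(split(df, factor(df$sample_id, levels = unique(df$sample_id))),
           function(d) {
        counts <- setNames(vector("list", length(markerNames(panel))),
                           markerNames(panel))
        for (mk in unique(d$marker)) {
            dm <- d[d$marker == mk & d$count > 0, ]
            counts[[mk]] <- setNames(as.integer(dm$count),
                                     as.character(dm$length))
        }
        counts[vapply(counts, is.null, logical(1))] <-
            list(setNames(integer(0), character(0)))
        SampleSpectra(d$sample_id[1L], counts)
    })
}

#' @rdname readSpectraTsv
#' @param spectra a \linkS4class{SampleSpectra} or list of them.
#' @export
writeSpectraTsv <- function(spectra, path) {
    if (is(spectra, "SampleSpectra")) spectra <- list(spectra)
    rows <- lapply(spectra, function(s) {
        per <- lapply(names(s@counts), function(mk) {
            v <- s@counts[[mk]]
            if (!length(v)) return(NULL)
            data.frame(sample_id = s@sample_id, marker = mk,
                       length = as.integer(names(v)),
                       count = as.integer(v), stringsAsFactors = FALSE)
        })
        do.call(rbind, per)
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
        df <- data.frame(sample_id = character(0), marker = character(0),
                         length = integer(0), count = integer(0))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
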