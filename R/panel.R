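#' Construct a marker panel
#'
#' @param markers data.frame with columns \code{name}, \code{repeat_unit},
#'   \code{ref_length} (repeat units in the reference allele), \code{flank5},
#'   \code{flank3}.
#' @param version free-text version label.
#' @return a validated \linkS4class{MarkerPanel}.
#' @examples
#' MarkerPanel(data.frame(name = "M1", repeat_unit = "A", ref_length = 20,
#'                        flank5 = "TTGATTAACCCG", flank3 = "AACTTCGAAGAG"))
#' @export
MarkerPanel <- function(markers, version = "custom") {
    markers <- as.data.frame(markers, stringsAsFactors = FALSE)
    if ("ref_length" %in% names(markers))
        markers$ref_length <- as.integer(markers$ref_length)
    obj <- new("MarkerPanel", markers = markers, version = version)
    obj
}

# 14 synthetic poly-A markers. The clinical panel's marker identities are not
# public; the classifier and simulator only need repeat lengths and unique
# anchoring flanks, so the shipped default is an explicitly synthetic
# stand-in spanning reference lengths 18-27 units.
.DEFAULT_PANEL <- data.frame(
    name = sprintf("MONO%02d", 1:14),
    repeat_unit = "A",
    ref_length = c(18L, 21L, 24L, 27L, 19L, 22L, 25L, 20L, 23L, 26L,
                   18L, 21L, 24L, 27L),
    flank5 = c("TTGATTAACCCG", "GACATGGCGCTT", "GACGTAACGTAT",
               "CGGTTGTTGCCC", "TAATCATTCAGA", "CCGTTTGGTGAT",
               "AAGGCCTGTGAG", "AGGACCGCACGT", "CCCATTGCTCGT",
               "CATAGCCATCCG", "AGTCCTTGGAGT", "TGCCTCAGCACG",
               "AGAATATCACGC", "CCACCGTTTGTT"),
    flank3 = c("AACTTCGAAGAG", "ACTGCCGCATCC", "CACCCTGTTTAT",
               "AGATTTAGGCCG", "GGGGCCTAGTCC", "GATGCGCCGGTG",
               "CCATGCGCGGAA", "TTGGCTATCGGT", "GTTCTCCCCCGC",
               "GACACGGAGCTC", "GCTCTAGTAGTC", "TATTCAATGCCT",
               "GGTTATATTTCA", "TAGCTGAGTCGT"),
    stringsAsFactors = FALSE)

#' The default 14-marker mononucleotide panel
#'
#' A synthetic stand-in panel of 14 poly-A markers with reference repeat
#' lengths between 18 and 27 units and unique 12-nt anchoring flanks. It
#' mirrors the size and mononucleotide composition of clinical MSI amplicon
#' panels without claiming their genomic loci.
#'
#' @return a \linkS4class{MarkerPanel} of 14 markers.
#' @examples
#' defaultPanel()
#' @export
defaultPanel <- function() MarkerPanel(.DEFAULT_PANEL, version = "synthetic-14-v1")

#' Read a marker panel from a tab-delimited file
#'
#' The file has a header row \code{name, repeat_unit, ref_length, flank5,
#' flank3} (tab-separated); lines starting with \code{#} are ignored. Marker
#' order in the file is preserved.
#'
#' @param path path to the panel TSV.
#' @return a validated \linkS4class{MarkerPanel}.
#' @seealso [writePanel()], [defaultPanel()]
#' @export
loadPanel <- function(path) {
    if (!file.exists(path))
        stopValidation("panel file not found: ", path)
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) < 2L)
        stopValidation("panel file has no marker rows: ", path)
    need <- c("name", "repeat_unit", "ref_length", "flank5", "flank3")
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (!identical(header, need))
        stopValidation("panel header must be: ", paste(need, collapse = ", "))
    rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
    bad <- which(lengths(rows) != 5L)
    if (length(bad))
        stopValidation("malformed panel row at line ", bad[1L] + 1L,
                       " (expected 5 tab-separated fields)")
    m <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(m) <- need
    rl <- suppressWarnings(as.integer(m$ref_length))
    if (anyNA(rl))
        stopValidation("non-integer ref_length at line ",
                       which(is.na(rl))[1L] + 1L)
    m$ref_length <- rl
    tryCatch(MarkerPanel(m, version = basename(path)),
             error = function(e) stopValidation(conditionMessage(e)))
}

#' Write a marker panel to a tab-delimited file
#'
#' @param panel a \linkS4class{MarkerPanel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePanel <- function(panel, path) {
    stopifnot(is(panel, "MarkerPanel"))
    utils::write.table(panel@markers, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @describeIn MarkerPanel marker names, in panel order.
#' @param x a \linkS4class{MarkerPanel}.
#' @export
setMethod("markerNames", "MarkerPanel", function(x) x@markers$name)

#' Panel marker table
#'
#' @param panel a \linkS4class{MarkerPanel}.
#' @return the marker data.frame (copy).
#' @export
panelMarkers <- function(panel) {
    stopifnot(is(panel, "MarkerPanel"))
    panel@markers
}

setMethod("show", "MarkerPanel", function(object) {
    cat("MarkerPanel '", object@version, "' with ", nrow(object@markers),
        " markers\n", sep = "")
    cat("  units: ", paste(unique(object@markers$repeat_unit), collapse = ","),
        "; ref lengths ", min(object@markers$ref_length), "-",
        max(object@markers$ref_length), " units\n", sep = "")
})
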