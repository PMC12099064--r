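#' Marker names of an object
#'
#' @param x a \linkS4class{MarkerPanel}, \linkS4class{SampleSpectra} or
#'   \linkS4class{MsiModel}.
#' @return character vector of marker names, in panel order.
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' Sample identifier
#'
#' @param x a \linkS4class{SampleSpectra} or \linkS4class{MsiResult}.
#' @return single character sample id.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' Per-marker read depths
#'
#' @param x a \linkS4class{SampleSpectra}.
#' @return named integer vector of total assigned reads per marker.
#' @export
setGeneric("spectraDepths", function(x) standardGeneric("spectraDepths"))

#' Median per-marker read depth (lower-median convention)
#'
#' For an even number of markers the lower of the two central order
#' statistics is used, a conservative convention for depth QC.
#'
#' @param x a \linkS4class{SampleSpectra}.
#' @return single integer median depth.
#' @export
setGeneric("medianDepth", function(x) standardGeneric("medianDepth"))

#' MSI call of a result
#'
#' @param x a \linkS4class{MsiResult}.
#' @return one of "MSI-H", "MSS", "uncertain", "fail".
#' @export
setGeneric("msiCall", function(x) standardGeneric("msiCall"))
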