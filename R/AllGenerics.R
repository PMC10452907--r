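#' @rdname SpcExperiment-class
#' @param x an object.
#' @export
setGeneric("spcLevel", function(x) standardGeneric("spcLevel"))

#' @rdname PresencePartition-class
#' @param x an object.
#' @export
setGeneric("identifiedSets", function(x) standardGeneric("identifiedSets"))

#' @rdname PresencePartition-class
#' @export
setGeneric("vennRegions", function(x) standardGeneric("vennRegions"))

#' @rdname PresencePartition-class
#' @export
setGeneric("hrProteins", function(x) standardGeneric("hrProteins"))

#' @rdname PresencePartition-class
#' @export
setGeneric("specificHR", function(x) standardGeneric("specificHR"))

#' @rdname PresencePartition-class
#' @export
setGeneric("commonAllSamples", function(x) standardGeneric("commonAllSamples"))

#' @rdname PresencePartition-class
#' @export
setGeneric("commonAtLeastOnce", function(x) standardGeneric("commonAtLeastOnce"))
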