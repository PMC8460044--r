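#' @rdname CircleSet-class
#' @param x,object a `CircleSet`
#' @export
setGeneric("circleIds", function(x) standardGeneric("circleIds"))

#' @rdname CircleSet-class
#' @export
setGeneric("circleSeqs", function(x) standardGeneric("circleSeqs"))

#' @rdname CircleSet-class
#' @export
setGeneric("circleInfo", function(x) standardGeneric("circleInfo"))

#' @rdname CircleSet-class
#' @export
setGeneric("hasHim", function(x) standardGeneric("hasHim"))

#' @rdname CircleSet-class
#' @export
setGeneric("himTruth", function(x) standardGeneric("himTruth"))

#' @rdname HostGenome-class
#' @param x,object a `HostGenome`
#' @export
setGeneric("hostSeqs", function(x) standardGeneric("hostSeqs"))

#' @rdname HostGenome-class
#' @export
setGeneric("hostGenes", function(x) standardGeneric("hostGenes"))

#' @rdname HostGenome-class
#' @export
setGeneric("scaffoldLengths", function(x) standardGeneric("scaffoldLengths"))

#' @rdname BreakSiteProfile-class
#' @param x,object a `BreakSiteProfile`
#' @export
setGeneric("nChimeras", function(x) standardGeneric("nChimeras"))

#' @rdname BreakSiteProfile-class
#' @export
setGeneric("modalPair", function(x) standardGeneric("modalPair"))

#' @rdname BreakSiteProfile-class
#' @export
setGeneric("conservedFraction", function(x) standardGeneric("conservedFraction"))

#' @rdname IntegrationIndexSeries-class
#' @param x,object an `IntegrationIndexSeries`
#' @export
setGeneric("indexTable", function(x) standardGeneric("indexTable"))

#' @rdname IntegrationIndexSeries-class
#' @export
setGeneric("timingClass", function(x) standardGeneric("timingClass"))
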