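#' @include AllClasses.R
NULL

#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("sampleRoster", function(x) standardGeneric("sampleRoster"))
#' @export
setGeneric("mutationRecords", function(x) standardGeneric("mutationRecords"))
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))
#' @export
setGeneric("synonymMap", function(x) standardGeneric("synonymMap"))
#' @export
setGeneric("siteWeights", function(x) standardGeneric("siteWeights"))
#' @export
setGeneric("preliminaryWeightsOf", function(x) standardGeneric("preliminaryWeightsOf"))
#' @export
setGeneric("qValue", function(x) standardGeneric("qValue"))
#' @export
setGeneric("mutatedSamples", function(x, gene) standardGeneric("mutatedSamples"))
#' @export
setGeneric("mutationCounts", function(x) standardGeneric("mutationCounts"))
#' @export
setGeneric("recordCounts", function(x) standardGeneric("recordCounts"))
#' @export
setGeneric("trueProb", function(x) standardGeneric("trueProb"))
#' @export
setGeneric("trueWeighted", function(x, weights) standardGeneric("trueWeighted"))
#' @export
setGeneric("callerId", function(x) standardGeneric("callerId"))
#' @export
setGeneric("geneCalls", function(x) standardGeneric("geneCalls"))
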