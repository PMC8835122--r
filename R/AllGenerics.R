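#' @include coexminer-package.R
NULL

#' @export
setGeneric("nTransactions", function(x) standardGeneric("nTransactions"))

#' @export
setGeneric("nMultiAgent", function(x) standardGeneric("nMultiAgent"))

#' @export
setGeneric("agentUniverse", function(x) standardGeneric("agentUniverse"))

#' @export
setGeneric("wsInfo", function(x) standardGeneric("wsInfo"))

#' @export
setGeneric("recordCounts", function(x) standardGeneric("recordCounts"))

#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @export
setGeneric("agentSets", function(x) standardGeneric("agentSets"))

#' @export
setGeneric("itemList", function(x) standardGeneric("itemList"))

#' @export
setGeneric("wsCount", function(x) standardGeneric("wsCount"))

#' @export
setGeneric("supportValues", function(x) standardGeneric("supportValues"))

#' @export
setGeneric("denominatorKind", function(x) standardGeneric("denominatorKind"))

#' @export
setGeneric("denominatorCount", function(x) standardGeneric("denominatorCount"))

#' @export
setGeneric("antecedents", function(x) standardGeneric("antecedents"))

#' @export
setGeneric("consequents", function(x) standardGeneric("consequents"))

#' @export
setGeneric("cooccurrenceCounts", function(x, masked = TRUE)
    standardGeneric("cooccurrenceCounts"))
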