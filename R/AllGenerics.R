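#' @rdname CausalGraph-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname CausalGraph-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname CausalGraph-accessors
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))

#' @rdname CausalGraph-accessors
#' @export
setGeneric("arcConfidences", function(x) standardGeneric("arcConfidences"))

#' @rdname CausalGraph-accessors
#' @export
setGeneric("graphOrigin", function(x) standardGeneric("graphOrigin"))

#' @rdname mutilate
#' @export
setGeneric("mutilate", function(g, u) standardGeneric("mutilate"))

#' @rdname InterventionSet-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname InterventionSet-accessors
#' @export
setGeneric("interventionKind", function(x) standardGeneric("interventionKind"))

#' @rdname PerturbationDataset-accessors
#' @export
setGeneric("initialState", function(x) standardGeneric("initialState"))

#' @rdname PerturbationDataset-accessors
#' @export
setGeneric("outcomeState", function(x) standardGeneric("outcomeState"))

#' @rdname PerturbationDataset-accessors
#' @export
setGeneric("interventionSets", function(x) standardGeneric("interventionSets"))

#' @rdname PerturbationDataset-accessors
#' @export
setGeneric("sampleKind", function(x) standardGeneric("sampleKind"))

#' @rdname PerturbationDataset-accessors
#' @export
setGeneric("sampleContext", function(x) standardGeneric("sampleContext"))

#' @rdname PerturbagenRanking-accessors
#' @export
setGeneric("rankedNodes", function(x) standardGeneric("rankedNodes"))

#' @rdname PerturbagenRanking-accessors
#' @export
setGeneric("nodeScores", function(x) standardGeneric("nodeScores"))
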