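# Accessor generics. Slot access from user code is discouraged; these are the
# supported surface.

#' @rdname OmicsMatrix-class
#' @param x an object.
#' @export
setGeneric("omicsType", function(x) standardGeneric("omicsType"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname Hypergraph-class
#' @param x an object.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname Hypergraph-class
#' @export
setGeneric("partnerIds", function(x) standardGeneric("partnerIds"))

#' @rdname Hypergraph-class
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))

#' @rdname Hypergraph-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname Hypergraph-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname Hypergraph-class
#' @export
setGeneric("centralCluster", function(x) standardGeneric("centralCluster"))

#' @rdname RFReport-class
#' @param x an object.
#' @export
setGeneric("oobConfusion", function(x) standardGeneric("oobConfusion"))

#' @rdname RFReport-class
#' @export
setGeneric("oobErrorRate", function(x) standardGeneric("oobErrorRate"))

#' @rdname RFReport-class
#' @export
setGeneric("oobVotes", function(x) standardGeneric("oobVotes"))

#' @rdname RFReport-class
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname RFReport-class
#' @export
setGeneric("oobAUC", function(x) standardGeneric("oobAUC"))

#' @rdname RFReport-class
#' @export
setGeneric("featureImportance", function(x) standardGeneric("featureImportance"))

#' @rdname BorutaResult-class
#' @param x an object.
#' @export
setGeneric("borutaStatus", function(x) standardGeneric("borutaStatus"))

#' @rdname BorutaResult-class
#' @export
setGeneric("hitCounts", function(x) standardGeneric("hitCounts"))

#' @rdname SyntheticCohort-class
#' @param x an object.
#' @export
setGeneric("growthTable", function(x) standardGeneric("growthTable"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("phenotypeTable", function(x) standardGeneric("phenotypeTable"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("methylationMatrix", function(x) standardGeneric("methylationMatrix"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
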