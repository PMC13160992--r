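#' Accessors for SSRFeatureSet and result classes
#'
#' \code{presenceMatrix} returns the binary features x samples matrix;
#' \code{featureKeys} the canonical \code{"locus|motif|count"} keys;
#' \code{sampleGroups} the named vector of origin groups;
#' \code{groupNames} the distinct groups in order of first appearance.
#'
#' @param x an \code{\linkS4class{SSRFeatureSet}}.
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureKeys", function(x) standardGeneric("featureKeys"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname accessors
#' @export
setMethod("presenceMatrix", "SSRFeatureSet", function(x)
    SummarizedExperiment::assay(x, "presence"))

#' @rdname accessors
#' @export
setMethod("featureKeys", "SSRFeatureSet", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleGroups", "SSRFeatureSet", function(x) {
    g <- SummarizedExperiment::colData(x)$group
    names(g) <- colnames(x)
    g
})

#' @rdname accessors
#' @export
setMethod("groupNames", "SSRFeatureSet", function(x)
    unique(SummarizedExperiment::colData(x)$group))

#' Selected features and scores of a selection result
#'
#' @param x an \code{\linkS4class{SSRSelection}}.
#' @return \code{selectedFeatures}: character vector of feature keys (most
#'   informative first); \code{selectionScores}: aligned numeric scores;
#'   \code{selectionMethod}: the strategy name.
#' @name selection-accessors
NULL

#' @rdname selection-accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname selection-accessors
#' @export
setGeneric("selectionScores", function(x) standardGeneric("selectionScores"))

#' @rdname selection-accessors
#' @export
setGeneric("selectionMethod", function(x) standardGeneric("selectionMethod"))

#' @rdname selection-accessors
#' @export
setMethod("selectedFeatures", "SSRSelection", function(x) x@features)

#' @rdname selection-accessors
#' @export
setMethod("selectionScores", "SSRSelection", function(x) {
    s <- x@scores
    names(s) <- x@features
    s
})

#' @rdname selection-accessors
#' @export
setMethod("selectionMethod", "SSRSelection", function(x) x@method)

#' Group attribution of a group-wise conserved selection
#'
#' @param x an \code{\linkS4class{SSRSelection}} produced by
#'   \code{\link{gcSSRSelect}}.
#' @return named list: feature key -> character vector of groups in which the
#'   feature is conserved.
#' @export
setGeneric("groupAttribution", function(x) standardGeneric("groupAttribution"))

#' @rdname groupAttribution
#' @export
setMethod("groupAttribution", "SSRSelection", function(x) x@groupAttribution)
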