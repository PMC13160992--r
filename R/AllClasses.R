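#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' SSRFeatureSet: binary SSR presence/absence markers with origin labels
#'
#' An \code{SSRFeatureSet} extends
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}} and stores one
#' binary assay, \code{"presence"}, with SSR features as rows and samples as
#' columns. Each feature is keyed by the triple (locus, motif, repeat count);
#' the three components are kept in \code{rowData} and serialise to the
#' canonical key \code{"locus|motif|count"}. Sample origin groups live in
#' \code{colData(x)$group}.
#'
#' @slot .. see \code{SummarizedExperiment}; no extra slots are added.
#' @seealso \code{\link{SSRFeatureSet}} (constructor),
#'   \code{\link{presenceMatrix}}, \code{\link{featureKeys}},
#'   \code{\link{sampleGroups}}
#' @export
setClass("SSRFeatureSet", contains = "SummarizedExperiment")

setValidity("SSRFeatureSet", function(object) {
    msg <- character()
    if (!"presence" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'presence' is required")
    else {
        v <- SummarizedExperiment::assay(object, "presence")
        if (!all(v %in% c(0L, 1L)))
            msg <- c(msg, "'presence' values must be binary (0/1)")
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("locus_id", "motif", "repeat_count")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, sprintf("rowData must contain %s",
                              paste(need, collapse = ", ")))
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate feature keys")
    if (length(msg)) msg else TRUE
})

#' Construct an SSRFeatureSet
#'
#' @param presence binary matrix, features in rows (rownames are
#'   \code{"locus|motif|count"} keys) and samples in columns.
#' @param groups named character vector or factor mapping each sample id
#'   (column of \code{presence}) to its origin group.
#' @return An \code{\linkS4class{SSRFeatureSet}}.
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("LOC1|AG|5", "LOC2|TCA|4"), c("s1", "s2")))
#' fs <- SSRFeatureSet(m, c(s1 = "MP", s2 = "CO"))
#' @export
SSRFeatureSet <- function(presence, groups) {
    presence <- as.matrix(presence)
    storage.mode(presence) <- "integer"
    if (is.null(rownames(presence)) || is.null(colnames(presence)))
        stop("'presence' must have feature-key rownames and sample colnames")
    if (!all(colnames(presence) %in% names(groups)))
        stop("unlabelled sample(s): ",
             paste(setdiff(colnames(presence), names(groups)), collapse = ", "))
    groups <- as.character(groups[colnames(presence)])
    parts <- parseFeatureKey(rownames(presence))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(presence = presence),
        rowData = DataFrame(locus_id = parts$locus_id, motif = parts$motif,
                            repeat_count = parts$repeat_count,
                            row.names = rownames(presence)),
        colData = DataFrame(group = groups, row.names = colnames(presence)))
    new("SSRFeatureSet", se)
}

#' SSRSelection: an ordered, scored SSR subset from one selection strategy
#'
#' @slot method one of \code{"gc_ssr"}, \code{"select_k_best"},
#'   \code{"hybrid"}, \code{"lasso"}.
#' @slot features ordered character vector of feature keys, most informative
#'   first.
#' @slot scores numeric scores aligned with \code{features} (F-values,
#'   importances, or absolute coefficients; group counts for gc_ssr).
#' @slot params list; the configuration the strategy ran with.
#' @slot groupAttribution (gc_ssr only) named list mapping each retained
#'   feature key to the set of groups in which it is conserved.
#' @export
setClass("SSRSelection",
    representation(method = "character", features = "character",
                   scores = "numeric", params = "list",
                   groupAttribution = "list"),
    prototype(groupAttribution = list()))

setValidity("SSRSelection", function(object) {
    msg <- character()
    if (!object@method %in% c("gc_ssr", "select_k_best", "hybrid", "lasso"))
        msg <- c(msg, "unknown method")
    if (anyDuplicated(object@features))
        msg <- c(msg, "duplicate features")
    if (length(object@scores) != length(object@features))
        msg <- c(msg, "scores not aligned with features")
    if (length(msg)) msg else TRUE
})

#' LassoModel: one-vs-rest L1-penalised logistic model
#'
#' @slot weights K x m coefficient matrix (classes in rows, features in
#'   columns).
#' @slot intercepts length-K numeric.
#' @slot lambda non-negative regularisation strength multiplying the L1 norm
#'   in \code{\link{lassoLoss}}.
#' @slot classes class order (rows of \code{weights}).
#' @slot featureOrder feature-key order (columns of \code{weights}).
#' @slot tuning list with the LOOCV search trace (candidate inverse
#'   regularisation values and their weighted-F1 scores).
#' @export
setClass("LassoModel",
    representation(weights = "matrix", intercepts = "numeric",
                   lambda = "numeric", classes = "character",
                   featureOrder = "character", tuning = "list"),
    prototype(tuning = list()))

setValidity("LassoModel", function(object) {
    msg <- character()
    if (nrow(object@weights) != length(object@classes))
        msg <- c(msg, "weights rows must match classes")
    if (ncol(object@weights) != length(object@featureOrder))
        msg <- c(msg, "weights columns must match featureOrder")
    if (length(object@intercepts) != length(object@classes))
        msg <- c(msg, "one intercept per class required")
    if (object@lambda < 0) msg <- c(msg, "lambda must be non-negative")
    if (length(msg)) msg else TRUE
})

#' ClassifierSpec: a classifier kind plus hyperparameters
#'
#' @slot kind \code{"linear_svc"}, \code{"random_forest"} or
#'   \code{"gradient_boosting"}.
#' @slot hyperparameters named list (kind-specific, see
#'   \code{\link{classifierSearchSpace}}).
#' @slot classWeightBalanced logical; balanced class weights (default TRUE
#'   for linear_svc and random_forest, FALSE for gradient_boosting).
#' @slot seed integer seed used for all model randomness.
#' @export
setClass("ClassifierSpec",
    representation(kind = "character", hyperparameters = "list",
                   classWeightBalanced = "logical", seed = "integer"))

setValidity("ClassifierSpec", function(object) {
    if (!object@kind %in% c("linear_svc", "random_forest",
                            "gradient_boosting"))
        "unknown classifier kind" else TRUE
})

#' SSRLearningCurve: per-k replicate metrics along an RFE ranking
#'
#' @slot k integer vector 1..k_max.
#' @slot means,sds k_max x 4 matrices (columns weighted_f1, accuracy,
#'   weighted_precision, weighted_recall): mean and SD over replicates.
#' @slot featuresAtK list; element k is the top-k feature prefix.
#' @slot confusionByK list of K x K replicate-averaged confusion matrices
#'   (true classes in rows).
#' @slot meanConfusion K x K matrix averaged over replicates and k.
#' @slot replicates number of replicates per k.
#' @export
setClass("SSRLearningCurve",
    representation(k = "integer", means = "matrix", sds = "matrix",
                   featuresAtK = "list", confusionByK = "list",
                   meanConfusion = "matrix", replicates = "integer"))

setValidity("SSRLearningCurve", function(object) {
    msg <- character()
    if (any(object@sds < 0)) msg <- c(msg, "negative SD")
    if (length(object@featuresAtK) != length(object@k))
        msg <- c(msg, "featuresAtK misaligned with k")
    if (length(object@k) > 1) {
        for (i in seq_len(length(object@k) - 1L)) {
            a <- object@featuresAtK[[i]]; b <- object@featuresAtK[[i + 1L]]
            if (!identical(a, b[seq_along(a)]))
                msg <- c(msg, "feature lists are not nested prefixes")
        }
    }
    if (length(msg)) msg[1] else TRUE
})

#' SSRBenchResult: one (selection, classifier) benchmark outcome
#'
#' @slot curve an \code{\linkS4class{SSRLearningCurve}}.
#' @slot bestK smallest k attaining the curve's maximum mean weighted F1.
#' @slot bestFeatures the top-bestK features.
#' @slot meanConfusion replicate-and-k-averaged confusion matrix.
#' @slot importances named numeric; feature importances from a full-data fit
#'   at bestK.
#' @slot selectionMethod,classifierKind provenance strings.
#' @export
setClass("SSRBenchResult",
    representation(curve = "SSRLearningCurve", bestK = "integer",
                   bestFeatures = "character", meanConfusion = "matrix",
                   importances = "numeric", selectionMethod = "character",
                   classifierKind = "character"))

#' SSRPCoAResult: principal coordinate analysis of a distance matrix
#'
#' @slot coordinates n x p matrix (axes with positive eigenvalues only),
#'   columns centred.
#' @slot eigenvalues all eigenvalues, descending (negative ones included).
#' @slot proportionExplained per retained axis, computed over the positive
#'   eigenvalues only.
#' @export
setClass("SSRPCoAResult",
    representation(coordinates = "matrix", eigenvalues = "numeric",
                   proportionExplained = "numeric"))

setValidity("SSRPCoAResult", function(object) {
    msg <- character()
    if (any(object@proportionExplained < 0))
        msg <- c(msg, "negative proportion explained")
    if (sum(object@proportionExplained) > 1 + 1e-8)
        msg <- c(msg, "proportions sum above 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SSRFeatureSet", function(object) {
    cat(sprintf("SSRFeatureSet: %d features x %d samples\n",
                nrow(object), ncol(object)))
    grp <- table(sampleGroups(object))
    cat("groups:", paste(sprintf("%s (n=%d)", names(grp), as.integer(grp)),
                         collapse = ", "), "\n")
})

setMethod("show", "SSRSelection", function(object) {
    cat(sprintf("SSRSelection [%s]: %d features\n", object@method,
                length(object@features)))
    if (length(object@features))
        cat("top:", paste(utils::head(object@features, 5), collapse = ", "),
            if (length(object@features) > 5) "..." else "", "\n")
})

setMethod("show", "LassoModel", function(object) {
    cat(sprintf("LassoModel: %d classes x %d features, lambda = %.4g, %d non-zero weights\n",
                nrow(object@weights), ncol(object@weights), object@lambda,
                sum(object@weights != 0)))
})

setMethod("show", "ClassifierSpec", function(object) {
    cat(sprintf("ClassifierSpec [%s]%s, seed %d\n", object@kind,
                if (object@classWeightBalanced) " (balanced weights)" else "",
                object@seed))
    if (length(object@hyperparameters))
        cat("  ", paste(names(object@hyperparameters),
                        vapply(object@hyperparameters,
                               function(v) paste(format(v), collapse = ","),
                               ""), sep = "=", collapse = " "), "\n")
})

setMethod("show", "SSRLearningCurve", function(object) {
    cat(sprintf("SSRLearningCurve: k = 1..%d, %d replicates; max mean wF1 = %.3f\n",
                max(object@k), object@replicates,
                max(object@means[, "weighted_f1"])))
})

setMethod("show", "SSRBenchResult", function(object) {
    cat(sprintf("SSRBenchResult [%s x %s]: best k = %d, mean wF1 = %.3f\n",
                object@selectionMethod, object@classifierKind, object@bestK,
                object@curve@means[object@bestK, "weighted_f1"]))
})

setMethod("show", "SSRPCoAResult", function(object) {
    p <- object@proportionExplained
    cat(sprintf("SSRPCoAResult: %d samples, %d axes; axis 1-2 explain %.2f%% / %.2f%%\n",
                nrow(object@coordinates), ncol(object@coordinates),
                100 * p[1], if (length(p) > 1) 100 * p[2] else NA_real_))
})
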