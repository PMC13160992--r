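#' Read and write the package's plain-text interchange formats
#'
#' The feature-matrix CSV dialect has samples in rows: the first column is
#' \code{sample_id}, the second \code{group}, and the remaining columns are
#' \code{"locus|motif|count"} feature keys holding 0/1. Calls are written as
#' TSV; selections as JSON (method, params, ordered keys, scores) or as a
#' one-column CSV of keys; distance matrices as square CSV; PCoA results as
#' a coordinates CSV plus an eigenvalue/proportion sidecar JSON.
#'
#' @param x object to write (see individual functions).
#' @param path file path.
#' @return Readers return the corresponding object; writers return
#'   \code{invisible(path)}.
#' @name ssr-io
NULL

#' @rdname ssr-io
#' @export
writeFeatureMatrixCSV <- function(x, path) {
    m <- t(presenceMatrix(x))
    df <- data.frame(sample_id = rownames(m),
                     group = as.character(sampleGroups(x)[rownames(m)]),
                     m, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname ssr-io
#' @export
readFeatureMatrixCSV <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!identical(colnames(df)[1:2], c("sample_id", "group")))
        stop("feature-matrix CSV must start with sample_id,group columns")
    m <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(m) <- df$sample_id
    SSRFeatureSet(t(m), stats::setNames(df$group, df$sample_id))
}

#' @rdname ssr-io
#' @export
writeCallsTSV <- function(x, path) {
    utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname ssr-io
#' @export
readLabelsCSV <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% colnames(df)))
        stop("labels CSV needs sample_id and group columns")
    stats::setNames(df$group, df$sample_id)
}

#' @rdname ssr-io
#' @export
writeLabelsCSV <- function(x, path) {
    utils::write.csv(data.frame(sample_id = names(x),
                                group = as.character(x)),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname ssr-io
#' @export
writeSelectionJSON <- function(x, path) {
    stopifnot(methods::is(x, "SSRSelection"))
    obj <- list(method = x@method, params = x@params,
                features = x@features, scores = x@scores)
    if (length(x@groupAttribution))
        obj$group_attribution <- x@groupAttribution
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname ssr-io
#' @export
readSelectionJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    ga <- obj$group_attribution
    methods::new("SSRSelection", method = obj$method,
                 features = as.character(obj$features),
                 scores = as.numeric(obj$scores),
                 params = as.list(obj$params),
                 groupAttribution = if (is.null(ga)) list() else
                     lapply(ga, as.character))
}

#' @rdname ssr-io
#' @export
writeSelectionCSV <- function(x, path) {
    utils::write.csv(data.frame(feature_key = x@features), path,
                     row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname ssr-io
#' @export
writeDistanceCSV <- function(x, path) {
    m <- as.matrix(x)
    utils::write.csv(data.frame(sample_id = rownames(m), m,
                                check.names = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname ssr-io
#' @export
writePCoACSV <- function(x, path) {
    stopifnot(methods::is(x, "SSRPCoAResult"))
    co <- x@coordinates
    utils::write.csv(data.frame(sample_id = rownames(co), co,
                                check.names = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    sidecar <- sub("\\.csv$", "", path)
    jsonlite::write_json(list(eigenvalues = x@eigenvalues,
                              proportion_explained = x@proportionExplained),
                         paste0(sidecar, "_eigen.json"), digits = NA,
                         pretty = TRUE)
    invisible(path)
}
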