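#' Jaccard distances between samples over selected features
#'
#' Distance between two samples is one minus the ratio of shared to pooled
#' present features, \eqn{1 - |A \cap B| / |A \cup B|}. Two samples with no
#' present feature under the selected panel are at distance 0 (they are
#' identical under that panel).
#'
#' @param x an \code{\linkS4class{SSRFeatureSet}} or a binary samples x
#'   features matrix.
#' @param features optional feature keys restricting the panel.
#' @return A \code{\link[stats]{dist}} object over samples.
#' @export
jaccardDistance <- function(x, features = NULL) {
    if (methods::is(x, "SSRFeatureSet")) {
        if (!is.null(features)) x <- x[features, ]
        m <- t(presenceMatrix(x))
    } else m <- as.matrix(x)
    if (nrow(m) < 2) stop("at least two samples required")
    empty <- rowSums(m) == 0
    d <- suppressWarnings(vegan::vegdist(m, method = "jaccard",
                                         binary = TRUE))
    dm <- as.matrix(d)
    ## vegdist leaves NaN for pairs of empty samples; both-empty sets are
    ## identical under the panel
    dm[is.nan(dm)] <- 0
    diag(dm) <- 0
    stats::as.dist(dm)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centering of the squared
#' distances followed by a symmetric eigendecomposition. Axes with
#' positive eigenvalues are retained and scaled by the square root of
#' their eigenvalue; proportions explained are computed over the positive
#' eigenvalues only. Negative eigenvalues are reported unchanged (no
#' Lingoes or Cailliez correction).
#'
#' @param d a \code{\link[stats]{dist}} object or symmetric matrix.
#' @return An \code{\linkS4class{SSRPCoAResult}}.
#' @export
pcoaAnalysis <- function(d) {
    d <- stats::as.dist(d)
    n <- attr(d, "Size")
    if (is.null(n) || n < 2) stop("at least two samples required")
    res <- ape::pcoa(d)
    eig <- res$values$Eigenvalues
    pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
    co <- res$vectors[, seq_along(pos), drop = FALSE]
    colnames(co) <- paste0("Axis.", seq_along(pos))
    methods::new("SSRPCoAResult", coordinates = co,
                 eigenvalues = sort(eig, decreasing = TRUE),
                 proportionExplained = eig[pos] / sum(eig[pos]))
}

#' UPGMA hierarchical clustering
#'
#' Unweighted pair-group average linkage: repeatedly merges the pair of
#' clusters at minimal average distance, the merged cluster's distances
#' being size-weighted averages. Produces an ultrametric tree whose
#' cophenetic distance between two leaves is the height of their lowest
#' common merge. Ties between equally close pairs follow the merge order
#' of \code{\link[stats]{hclust}}.
#'
#' @param d a \code{\link[stats]{dist}} object or symmetric matrix.
#' @return An \code{\link[stats]{hclust}} tree; heights are merge heights
#'   and \code{\link[stats]{cophenetic}} recovers the cophenetic matrix.
#' @export
upgmaTree <- function(d) {
    d <- stats::as.dist(d)
    if (is.null(attr(d, "Size")) || attr(d, "Size") < 2)
        stop("at least two samples required")
    stats::hclust(d, method = "average")
}

#' Write and read UPGMA trees as Newick strings
#'
#' Branch lengths follow the edge-length convention in which each edge is
#' half the difference of the merge heights of its endpoints, so the
#' leaf-to-root path length equals half the merge height of the root (a
#' merge at distance 2 serialises as \code{"(A:1,B:1);"}).
#'
#' @param tree an \code{\link[stats]{hclust}} tree or
#'   \code{\link[ape]{phylo}} object.
#' @param path optional file; when given the string is also written there.
#' @param text a Newick string (alternative to \code{path}).
#' @return \code{writeNewick}: the Newick string, invisibly when written
#'   to a file. \code{readNewick}: an \code{\link[ape]{phylo}} tree.
#' @export
writeNewick <- function(tree, path = NULL) {
    ph <- if (inherits(tree, "phylo")) tree else ape::as.phylo(tree)
    s <- ape::write.tree(ph)
    if (!is.null(path)) {
        writeLines(s, path)
        return(invisible(s))
    }
    s
}

#' @rdname writeNewick
#' @export
readNewick <- function(text = NULL, path = NULL) {
    if (is.null(text) && is.null(path))
        stop("supply 'text' or 'path'")
    tr <- if (!is.null(text)) ape::read.tree(text = text) else
        ape::read.tree(path)
    if (is.null(tr)) {
        src <- if (!is.null(text)) text else path
        stop("malformed Newick input: ", substr(src, 1, 60))
    }
    tr
}
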