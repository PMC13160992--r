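#' Group-wise conserved SSR selection
#'
#' Retains a feature if and only if it is present in every sample of at
#' least one origin group, records all such groups per feature, and orders
#' the result by the number of attributed groups (descending), then by
#' feature key. No cap is applied: the natural output size of this filter
#' defines the cap used by the other selection strategies downstream.
#'
#' @param x an \code{\linkS4class{SSRFeatureSet}}.
#' @return An \code{\linkS4class{SSRSelection}} with method \code{"gc_ssr"};
#'   scores are the number of groups in which each feature is conserved and
#'   \code{\link{groupAttribution}} maps each feature to those groups.
#' @examples
#' sim <- simulateFeatureTable(simulationConfig(seed = 3))
#' sel <- gcSSRSelect(sim$features)
#' sel
#' @export
gcSSRSelect <- function(x) {
    m <- presenceMatrix(x)
    groups <- sampleGroups(x)
    gl <- groupNames(x)
    counts <- table(groups)
    if (any(counts == 0)) stop("empty group")
    conserved <- vapply(gl, function(g) {
        cols <- names(groups)[groups == g]
        rowSums(m[, cols, drop = FALSE]) == length(cols)
    }, logical(nrow(m)))
    if (is.null(dim(conserved)))
        conserved <- matrix(conserved, nrow = nrow(m),
                            dimnames = list(rownames(m), gl))
    nGroups <- rowSums(conserved)
    keep <- which(nGroups > 0)
    ord <- keep[order(-nGroups[keep], rownames(m)[keep])]
    feats <- rownames(m)[ord]
    attribution <- lapply(ord, function(i) gl[conserved[i, ]])
    names(attribution) <- feats
    methods::new("SSRSelection", method = "gc_ssr", features = feats,
                 scores = as.numeric(nGroups[ord]),
                 params = list(groups = as.character(gl)),
                 groupAttribution = attribution)
}

#' One-way ANOVA F-scores per feature
#'
#' Computes the classification F-value of each feature against the group
#' labels: between-group sum of squares over K-1 degrees of freedom divided
#' by within-group sum of squares over n-K. Features with zero within-group
#' variance but non-zero between-group variance score \code{Inf} (they sort
#' first); constant features score 0.
#'
#' @param x an \code{\linkS4class{SSRFeatureSet}}.
#' @return named numeric vector of F-values, one per feature.
#' @export
anovaFScores <- function(x) {
    m <- presenceMatrix(x)
    groups <- as.character(sampleGroups(x))
    gl <- unique(groups)
    K <- length(gl)
    n <- ncol(m)
    if (K < 2) stop("at least two groups required")
    if (n < 2) stop("at least two samples required")
    grand <- rowMeans(m)
    ssb <- numeric(nrow(m))
    ssw <- numeric(nrow(m))
    for (g in gl) {
        sub <- m[, groups == g, drop = FALSE]
        ng <- ncol(sub)
        mu <- rowMeans(sub)
        ssb <- ssb + ng * (mu - grand)^2
        ssw <- ssw + rowSums((sub - mu)^2)
    }
    f <- ifelse(ssw == 0 & ssb == 0, 0,
         ifelse(ssw == 0, Inf, (ssb / (K - 1)) / (ssw / (n - K))))
    names(f) <- rownames(m)
    f
}

#' Select the top-k features by ANOVA F-value
#'
#' Ties are broken by feature key in lexicographic order; infinite F-values
#' sort before all finite ones. Requesting more features than exist returns
#' all of them.
#'
#' @param x an \code{\linkS4class{SSRFeatureSet}}.
#' @param k number of features to keep (default 30).
#' @return An \code{\linkS4class{SSRSelection}} with method
#'   \code{"select_k_best"}.
#' @export
selectKBest <- function(x, k = 30L) {
    if (k < 1) stop("'k' must be at least 1")
    f <- anovaFScores(x)
    ord <- order(-f, names(f))
    keep <- utils::head(ord, k)
    methods::new("SSRSelection", method = "select_k_best",
                 features = names(f)[keep], scores = as.numeric(f[keep]),
                 params = list(k = as.integer(k)))
}

#' Default random-forest hyperparameter search space
#'
#' Ranges used by the hybrid selector's random search and by classifier
#' tuning for forests: number of trees 50-500, maximum depth 2-20, minimal
#' node size 1-5, and feature fraction per split drawn from sqrt, log2 or a
#' uniform fraction 0.1-1.0.
#'
#' @return list of sampling specifications, one per hyperparameter.
#' @export
forestSearchSpace <- function() {
    list(num_trees = c(50L, 500L),
         max_depth = c(2L, 20L),
         min_node_size = c(1L, 5L),
         feature_fraction = c("sqrt", "log2", "uniform"))
}

.sampleForestParams <- function(space) {
    ff <- sample(space$feature_fraction, 1L)
    list(num_trees = sample(space$num_trees[1]:space$num_trees[2], 1L),
         max_depth = sample(space$max_depth[1]:space$max_depth[2], 1L),
         min_node_size = sample(space$min_node_size[1]:
                                space$min_node_size[2], 1L),
         feature_fraction = if (ff == "uniform")
             stats::runif(1, 0.1, 1.0) else ff)
}

.mtryFromFraction <- function(frac, m) {
    if (identical(frac, "sqrt")) return(max(1L, floor(sqrt(m))))
    if (identical(frac, "log2")) return(max(1L, floor(log2(m))))
    max(1L, min(m, floor(as.numeric(frac) * m)))
}

## stratified fold assignment, deterministic under the active RNG state
.stratifiedFolds <- function(groups, folds) {
    assign <- integer(length(groups))
    for (g in unique(groups)) {
        idx <- which(groups == g)
        if (length(idx) < folds)
            stop("group '", g, "' has fewer samples (", length(idx),
                 ") than folds (", folds, "); reduce the fold count")
        assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    assign
}

.fitRanger <- function(X, y, params, seed, balanced = FALSE) {
    cw <- NULL
    if (balanced) {
        tab <- table(y)
        cw <- as.numeric(length(y) / (length(tab) * tab))
        names(cw) <- names(tab)
    }
    ranger::ranger(x = X, y = y,
                   num.trees = params$num_trees,
                   mtry = .mtryFromFraction(params$feature_fraction,
                                            ncol(X)),
                   min.node.size = params$min_node_size,
                   max.depth = params$max_depth,
                   importance = "impurity",
                   class.weights = cw,
                   seed = seed, num.threads = 1L)
}

#' Hybrid feature selection: filter, tune, then eliminate
#'
#' Three stages: (1) \code{\link{selectKBest}} reduces the table to the
#' \code{k1} highest-F features; (2) a seeded random search
#' (\code{search_iterations} draws, stratified \code{folds}-fold
#' cross-validation, weighted-F1 criterion) tunes a random forest over
#' \code{\link{forestSearchSpace}}; (3) recursive feature elimination with
#' step 1 using impurity importances reduces the set to \code{k2} features.
#'
#' @param x an \code{\linkS4class{SSRFeatureSet}}.
#' @param k1 stage-1 cap (default 5000).
#' @param k2 final subset size (default 30).
#' @param search_iterations random-search draws (default 150).
#' @param folds cross-validation folds for the search (default 4).
#' @param seed integer seed governing the search and all forest fits.
#' @return An \code{\linkS4class{SSRSelection}} with method
#'   \code{"hybrid"}; features are ordered by the final forest's importance
#'   (scores), surviving RFE.
#' @export
hybridSelect <- function(x, k1 = 5000L, k2 = 30L, search_iterations = 150L,
                         folds = 4L, seed = 1L) {
    if (k2 > k1) stop("'k2' must not exceed 'k1'")
    stage1 <- selectKBest(x, k = k1)
    sub <- x[stage1@features, ]
    X <- t(presenceMatrix(sub))
    y <- factor(as.character(sampleGroups(sub)))
    if (length(y) < folds) stop("fewer samples than folds")
    set.seed(seed)
    foldId <- .stratifiedFolds(as.character(y), folds)
    best <- NULL
    bestScore <- -Inf
    for (it in seq_len(search_iterations)) {
        params <- .sampleForestParams(forestSearchSpace())
        scores <- vapply(seq_len(folds), function(f) {
            tr <- foldId != f
            fit <- .fitRanger(X[tr, , drop = FALSE], droplevels(y[tr]),
                              params, seed = seed + it)
            pred <- stats::predict(fit,
                data = X[!tr, , drop = FALSE])$predictions
            computeMetrics(as.character(pred),
                           as.character(y[!tr]))["weighted_f1"]
        }, numeric(1))
        if (mean(scores) > bestScore) {
            bestScore <- mean(scores)
            best <- params
        }
    }
    ## stage 3: RFE down to k2 with the tuned forest
    remaining <- colnames(X)
    while (length(remaining) > k2) {
        fit <- .fitRanger(X[, remaining, drop = FALSE], y, best, seed = seed)
        imp <- fit$variable.importance[remaining]
        ## drop the least important feature; among ties the
        ## lexicographically greatest key goes first
        drop <- remaining[order(imp, remaining, method = "radix",
                                decreasing = c(FALSE, TRUE))][1]
        remaining <- setdiff(remaining, drop)
    }
    finalFit <- .fitRanger(X[, remaining, drop = FALSE], y, best,
                           seed = seed)
    imp <- finalFit$variable.importance[remaining]
    ord <- order(-imp, remaining)
    methods::new("SSRSelection", method = "hybrid",
                 features = remaining[ord], scores = as.numeric(imp[ord]),
                 params = list(k1 = as.integer(k1), k2 = as.integer(k2),
                               search_iterations =
                                   as.integer(search_iterations),
                               folds = as.integer(folds), seed = seed,
                               tuned = best, cv_weighted_f1 = bestScore))
}

## logistic sigmoid
.sigmoid <- function(z) 1 / (1 + exp(-z))

## fit one binary L1 logistic classifier (class vs rest) at a fixed
## penalty; glmnet needs >= 2 columns, so single-feature problems are
## padded with an all-zero dummy that cannot acquire weight
.fitBinaryLasso <- function(X, ybin, lambda) {
    pad <- ncol(X) == 1L
    if (pad) X <- cbind(X, `..dummy..` = 0)
    ## glmnet warns about small binomial classes on every LOOCV fold fit;
    ## small cohorts are this method's normal operating regime
    fit <- withCallingHandlers(
        glmnet::glmnet(X, ybin, family = "binomial", alpha = 1,
                       lambda = lambda, standardize = FALSE),
        warning = function(w) {
            if (grepl("fewer than 8", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    co <- as.numeric(stats::coef(fit))
    w <- co[-1]
    if (pad) w <- w[-length(w)]
    list(intercept = co[1], weights = w)
}

#' Fit a one-vs-rest L1-regularised logistic model with LOOCV tuning
#'
#' For each candidate inverse-regularisation value C (sampled log-uniformly
#' from \code{c_range}), every sample is held out in turn, K binary
#' class-vs-rest classifiers are fitted on the rest at penalty
#' \eqn{\lambda = 1/(n C)}, and the held-out prediction (argmax of the
#' normalised one-vs-rest probabilities) is recorded; candidates are scored
#' by the weighted F1 of the pooled predictions. The model is refitted on
#' all data at the best C (ties towards stronger regularisation).
#'
#' @param x an \code{\linkS4class{SSRFeatureSet}}.
#' @param c_range length-2 positive range of inverse-regularisation values
#'   (default \code{c(1e-3, 1e3)}).
#' @param search_iterations number of candidate values (default 25).
#' @param seed integer seed for the candidate draw.
#' @return A \code{\linkS4class{LassoModel}}.
#' @export
lassoFit <- function(x, c_range = c(1e-3, 1e3), search_iterations = 25L,
                     seed = 1L) {
    X <- t(presenceMatrix(x))
    y <- as.character(sampleGroups(x))
    classes <- unique(y)
    n <- nrow(X)
    if (n < length(classes) + 1) stop("too few samples to fit")
    tiny <- names(which(table(y) < 2))
    if (length(tiny))
        warning("class(es) with a single sample: ",
                paste(tiny, collapse = ", "),
                "; their held-out fold can never be predicted correctly")
    set.seed(seed)
    cands <- sort(exp(stats::runif(search_iterations, log(c_range[1]),
                                   log(c_range[2]))))
    scores <- vapply(cands, function(C) {
        lam <- 1 / ((n - 1) * C)
        preds <- vapply(seq_len(n), function(i) {
            dec <- vapply(classes, function(k) {
                ybin <- as.numeric(y[-i] == k)
                if (length(unique(ybin)) < 2) return(-Inf)
                fit <- .fitBinaryLasso(X[-i, , drop = FALSE], ybin, lam)
                fit$intercept + sum(fit$weights * X[i, ])
            }, numeric(1))
            classes[which.max(dec)]
        }, "")
        unname(computeMetrics(preds, y)["weighted_f1"])
    }, numeric(1))
    bestC <- cands[which.max(scores)]  # ties: smallest C (sorted ascending)
    lam <- 1 / (n * bestC)
    W <- matrix(0, length(classes), ncol(X),
                dimnames = list(classes, colnames(X)))
    b <- numeric(length(classes))
    for (ki in seq_along(classes)) {
        fit <- .fitBinaryLasso(X, as.numeric(y == classes[ki]), lam)
        W[ki, ] <- fit$weights
        b[ki] <- fit$intercept
    }
    methods::new("LassoModel", weights = W, intercepts = b, lambda = lam,
                 classes = classes, featureOrder = colnames(X),
                 tuning = list(candidates = cands, weighted_f1 = scores,
                               best_c = bestC, seed = seed))
}

#' Class probabilities from a one-vs-rest Lasso model
#'
#' Per-class sigmoid scores of the binary classifiers, normalised across
#' classes so every row sums to one.
#'
#' @param model a \code{\linkS4class{LassoModel}}.
#' @param x an \code{\linkS4class{SSRFeatureSet}} or a samples x features
#'   binary matrix whose columns match \code{model@featureOrder}.
#' @return n x K matrix of probabilities.
#' @export
predictProba <- function(model, x) {
    X <- if (methods::is(x, "SSRFeatureSet")) t(presenceMatrix(x)) else
        as.matrix(x)
    if (!identical(colnames(X), model@featureOrder)) {
        if (!all(model@featureOrder %in% colnames(X)))
            stop("feature mismatch between model and data")
        X <- X[, model@featureOrder, drop = FALSE]
    }
    raw <- .sigmoid(sweep(X %*% t(model@weights), 2, model@intercepts, "+"))
    p <- raw / rowSums(raw)
    colnames(p) <- model@classes
    rownames(p) <- rownames(X)
    p
}

#' Combined cross-entropy and L1 loss of a Lasso model
#'
#' Evaluates
#' \deqn{-\frac{1}{n}\sum_{i=1}^n \sum_{k=1}^K \mathbb{1}(y_i = k)
#'   \log p_{i,k} + \lambda \sum_{k=1}^K \sum_{j=1}^m |\omega_{k,j}|}
#' where the probabilities come from \code{\link{predictProba}} and are
#' clamped below at \code{1e-15}.
#'
#' @param model a \code{\linkS4class{LassoModel}}.
#' @param x data as in \code{\link{predictProba}}.
#' @param labels named character vector of true groups (defaults to the
#'   groups stored in \code{x} when it is an
#'   \code{\linkS4class{SSRFeatureSet}}).
#' @return A single non-negative number.
#' @export
lassoLoss <- function(model, x, labels = NULL) {
    if (is.null(labels)) {
        if (!methods::is(x, "SSRFeatureSet"))
            stop("'labels' required when 'x' is a plain matrix")
        labels <- as.character(sampleGroups(x))
    }
    p <- predictProba(model, x)
    if (!all(labels %in% model@classes))
        stop("label(s) outside the model's classes")
    idx <- cbind(seq_along(labels), match(labels, model@classes))
    ce <- -mean(log(pmax(p[idx], 1e-15)))
    ce + model@lambda * sum(abs(model@weights))
}

#' Lasso-based feature selection from non-zero coefficients
#'
#' Fits \code{\link{lassoFit}} and keeps every feature with at least one
#' non-zero coefficient, ranked by the maximum absolute coefficient across
#' classes (ties by feature key) and truncated at \code{cap}.
#'
#' @inheritParams lassoFit
#' @param cap maximum number of features returned (default 30).
#' @return An \code{\linkS4class{SSRSelection}} with method
#'   \code{"lasso"}; empty (with a warning) when every coefficient is zero.
#' @export
lassoSelect <- function(x, cap = 30L, c_range = c(1e-3, 1e3),
                        search_iterations = 25L, seed = 1L) {
    model <- lassoFit(x, c_range = c_range,
                      search_iterations = search_iterations, seed = seed)
    stat <- apply(abs(model@weights), 2, max)
    nz <- names(stat)[stat > 0]
    params <- list(cap = as.integer(cap), c_range = c_range,
                   search_iterations = as.integer(search_iterations),
                   seed = seed, best_c = model@tuning$best_c)
    if (!length(nz)) {
        warning("lasso selection is empty: all coefficients are zero")
        return(methods::new("SSRSelection", method = "lasso",
                            features = character(0), scores = numeric(0),
                            params = params))
    }
    ord <- nz[order(-stat[nz], nz)]
    ord <- utils::head(ord, cap)
    methods::new("SSRSelection", method = "lasso", features = ord,
                 scores = as.numeric(stat[ord]), params = params)
}
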