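#' Construct a classifier specification
#'
#' @param kind \code{"linear_svc"} (linear-kernel support vector
#'   classifier, one-vs-rest), \code{"random_forest"} or
#'   \code{"gradient_boosting"}.
#' @param hyperparameters named list; missing entries fall back to
#'   \code{\link{defaultHyperparameters}}.
#' @param class_weight_balanced balanced class weights; defaults to TRUE
#'   for the SVC and the forest, FALSE for boosting.
#' @param seed integer seed for all model randomness.
#' @return A \code{\linkS4class{ClassifierSpec}}.
#' @export
classifierSpec <- function(kind, hyperparameters = list(),
                           class_weight_balanced =
                               kind %in% c("linear_svc", "random_forest"),
                           seed = 1L) {
    hp <- utils::modifyList(defaultHyperparameters(kind), hyperparameters)
    methods::new("ClassifierSpec", kind = kind, hyperparameters = hp,
                 classWeightBalanced = isTRUE(class_weight_balanced),
                 seed = as.integer(seed))
}

#' Default hyperparameters per classifier kind
#'
#' @param kind classifier kind.
#' @return named list of defaults.
#' @export
defaultHyperparameters <- function(kind) {
    switch(kind,
        linear_svc = list(cost = 1),
        random_forest = list(num_trees = 300L, max_depth = 0L,
                             min_node_size = 1L,
                             feature_fraction = "sqrt"),
        gradient_boosting = list(nrounds = 100L, eta = 0.3, max_depth = 3L,
                                 min_child_weight = 1, subsample = 1,
                                 colsample_bytree = 1),
        stop("unknown classifier kind: ", kind))
}

#' Hyperparameter search space per classifier kind
#'
#' Documented default spaces used by \code{\link{tuneClassifier}}:
#' linear SVC cost is drawn log-uniformly from 0.01-100; forests use
#' \code{\link{forestSearchSpace}}; gradient boosting draws rounds 50-300,
#' learning rate log-uniform 0.01-0.3, depth 2-8, subsample and column
#' subsample 0.5-1 and minimum child weight 1-5.
#'
#' @param kind classifier kind.
#' @return list describing the space.
#' @export
classifierSearchSpace <- function(kind) {
    switch(kind,
        linear_svc = list(cost = c(1e-2, 1e2)),
        random_forest = forestSearchSpace(),
        gradient_boosting = list(nrounds = c(50L, 300L),
                                 eta = c(0.01, 0.3),
                                 max_depth = c(2L, 8L),
                                 min_child_weight = c(1L, 5L),
                                 subsample = c(0.5, 1),
                                 colsample_bytree = c(0.5, 1)),
        stop("unknown classifier kind: ", kind))
}

.sampleParams <- function(kind) {
    sp <- classifierSearchSpace(kind)
    switch(kind,
        linear_svc = list(cost = exp(stats::runif(1, log(sp$cost[1]),
                                                  log(sp$cost[2])))),
        random_forest = .sampleForestParams(sp),
        gradient_boosting = list(
            nrounds = sample(sp$nrounds[1]:sp$nrounds[2], 1L),
            eta = exp(stats::runif(1, log(sp$eta[1]), log(sp$eta[2]))),
            max_depth = sample(sp$max_depth[1]:sp$max_depth[2], 1L),
            min_child_weight = sample(sp$min_child_weight[1]:
                                      sp$min_child_weight[2], 1L),
            subsample = stats::runif(1, sp$subsample[1], sp$subsample[2]),
            colsample_bytree = stats::runif(1, sp$colsample_bytree[1],
                                            sp$colsample_bytree[2])))
}

## encode a parameter list as a numeric vector for the surrogate model
.encodeParams <- function(params) {
    vapply(params, function(v) {
        if (is.character(v))
            as.numeric(match(v, c("sqrt", "log2"), nomatch = 0L))
        else as.numeric(v)
    }, numeric(1))
}

## ---- unified fit / predict / importance over the three kinds ----

## fit counter used by the LOOCV contract tests
.fitCounter <- new.env(parent = emptyenv())
.fitCounter$n <- 0L

#' Number of model fits since the counter was last reset
#'
#' Instrumentation hook: every internal classifier fit increments a
#' counter, letting tests assert that leave-one-out evaluation trains
#' exactly n models per replicate.
#'
#' @param reset reset the counter to zero after reading.
#' @return integer count.
#' @export
fitCount <- function(reset = FALSE) {
    n <- .fitCounter$n
    if (reset) .fitCounter$n <- 0L
    n
}

.balancedWeights <- function(y) {
    tab <- table(y)
    w <- as.numeric(length(y) / (length(tab) * tab))
    names(w) <- names(tab)
    w
}

.fitClassifier <- function(spec, X, y, classes, seed = spec@seed) {
    .fitCounter$n <- .fitCounter$n + 1L
    hp <- spec@hyperparameters
    y <- as.character(y)
    set.seed(seed)
    if (spec@kind == "linear_svc") {
        comps <- lapply(classes, function(k) {
            pos <- y == k
            if (!any(pos) || all(pos)) return(NULL)  # class absent: -Inf
            y2 <- factor(ifelse(pos, "pos", "rest"),
                         levels = c("pos", "rest"))
            cw <- if (spec@classWeightBalanced) .balancedWeights(y2) else
                c(pos = 1, rest = 1)
            fit <- e1071::svm(X, y2, kernel = "linear", scale = FALSE,
                              cost = hp$cost, class.weights = cw)
            w <- as.numeric(t(fit$coefs) %*% fit$SV)
            names(w) <- colnames(X)
            rho <- fit$rho
            s <- as.numeric(X %*% w) - rho
            if (mean(s[pos]) < mean(s[!pos])) {  # orient: higher = class k
                w <- -w
                rho <- -rho
            }
            list(w = w, rho = rho)
        })
        names(comps) <- classes
        structure(list(kind = spec@kind, classes = classes,
                       components = comps, features = colnames(X)),
                  class = "ssr_classifier")
    } else if (spec@kind == "random_forest") {
        fit <- .fitRanger(X, factor(y), hp, seed = seed,
                          balanced = spec@classWeightBalanced)
        structure(list(kind = spec@kind, classes = classes, fit = fit,
                       features = colnames(X)),
                  class = "ssr_classifier")
    } else {
        lab <- match(y, classes) - 1L
        dtr <- xgboost::xgb.DMatrix(X, label = lab)
        params <- list(objective = "multi:softprob",
                       num_class = length(classes), eta = hp$eta,
                       max_depth = hp$max_depth,
                       min_child_weight = hp$min_child_weight,
                       subsample = hp$subsample,
                       colsample_bytree = hp$colsample_bytree,
                       nthread = 1L, seed = seed)
        fit <- xgboost::xgb.train(params = params, data = dtr,
                                  nrounds = hp$nrounds, verbose = 0)
        structure(list(kind = spec@kind, classes = classes, fit = fit,
                       features = colnames(X)),
                  class = "ssr_classifier")
    }
}

.predictClassifier <- function(model, X) {
    X <- X[, model$features, drop = FALSE]
    if (model$kind == "linear_svc") {
        dec <- vapply(model$classes, function(k) {
            cmp <- model$components[[k]]
            if (is.null(cmp)) return(rep(-Inf, nrow(X)))
            as.numeric(X %*% cmp$w) - cmp$rho
        }, numeric(nrow(X)))
        if (is.null(dim(dec))) dec <- matrix(dec, nrow = nrow(X))
        model$classes[max.col(dec, ties.method = "first")]
    } else if (model$kind == "random_forest") {
        as.character(stats::predict(model$fit, data = X)$predictions)
    } else {
        p <- stats::predict(model$fit, xgboost::xgb.DMatrix(X))
        model$classes[max.col(p, ties.method = "first")]
    }
}

## per-feature importance: SVC sums |coefficient| over the one-vs-rest
## component vectors; forests use impurity importance; boosting uses gain
.importanceClassifier <- function(model) {
    feats <- model$features
    imp <- stats::setNames(numeric(length(feats)), feats)
    if (model$kind == "linear_svc") {
        for (cmp in model$components)
            if (!is.null(cmp)) imp <- imp + abs(cmp$w)
    } else if (model$kind == "random_forest") {
        vi <- model$fit$variable.importance
        imp[names(vi)] <- vi
    } else {
        tab <- xgboost::xgb.importance(model = model$fit)
        if (nrow(tab)) imp[tab$Feature] <- tab$Gain
    }
    imp
}
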