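#' Weighted classification metrics from pooled predictions
#'
#' Computes accuracy and support-weighted precision, recall and F1 over
#' per-class scores. An unpredicted class has precision 0; a class whose
#' precision and recall are both 0 has F1 0.
#'
#' @param predictions,truth aligned character vectors.
#' @return named numeric vector: \code{weighted_f1}, \code{accuracy},
#'   \code{weighted_precision}, \code{weighted_recall}.
#' @examples
#' computeMetrics(c("a", "a", "b"), c("a", "b", "b"))
#' @export
computeMetrics <- function(predictions, truth) {
    if (length(predictions) == 0L) stop("empty input")
    if (length(predictions) != length(truth))
        stop("predictions and truth must be aligned")
    classes <- unique(truth)
    support <- as.numeric(table(factor(truth, classes)))
    prec <- rec <- f1 <- numeric(length(classes))
    for (i in seq_along(classes)) {
        k <- classes[i]
        tp <- sum(predictions == k & truth == k)
        npred <- sum(predictions == k)
        prec[i] <- if (npred == 0) 0 else tp / npred
        rec[i] <- tp / support[i]
        f1[i] <- if (prec[i] + rec[i] == 0) 0 else
            2 * prec[i] * rec[i] / (prec[i] + rec[i])
    }
    w <- support / sum(support)
    c(weighted_f1 = sum(w * f1),
      accuracy = mean(predictions == truth),
      weighted_precision = sum(w * prec),
      weighted_recall = sum(w * rec))
}

.confusion <- function(predictions, truth, classes) {
    table(factor(truth, classes), factor(predictions, classes))
}

#' Tune a classifier by cross-validated search
#'
#' Evaluates candidate hyperparameter configurations by mean weighted F1
#' over stratified cross-validation folds and returns the classifier
#' specification refitted with the best configuration. The incoming
#' (default) hyperparameters are always the first candidate evaluated, so
#' tuning can never fall below the untuned score on the same folds. The default
#' \code{"smbo"} method runs an initial random design and then proposes
#' each next candidate by maximising a random-forest surrogate of the
#' score over a random candidate pool; \code{"random"} draws every
#' candidate independently.
#'
#' @param spec a \code{\linkS4class{ClassifierSpec}}.
#' @param x an \code{\linkS4class{SSRFeatureSet}}.
#' @param features optional feature keys restricting the matrix.
#' @param iterations configurations to evaluate (default 100).
#' @param folds stratified CV folds (default 3).
#' @param method \code{"smbo"} or \code{"random"}.
#' @return The tuned \code{\linkS4class{ClassifierSpec}}; the evaluation
#'   trace is attached as \code{attr(, "tuning")}.
#' @export
tuneClassifier <- function(spec, x, features = NULL, iterations = 100L,
                           folds = 3L, method = c("smbo", "random")) {
    method <- match.arg(method)
    if (!is.null(features)) x <- x[features, ]
    X <- t(presenceMatrix(x))
    y <- as.character(sampleGroups(x))
    classes <- unique(y)
    set.seed(spec@seed)
    foldId <- .stratifiedFolds(y, folds)
    evalParams <- function(params) {
        cand <- classifierSpec(spec@kind, params,
                               spec@classWeightBalanced, spec@seed)
        scores <- vapply(seq_len(folds), function(f) {
            tr <- foldId != f
            fit <- .fitClassifier(cand, X[tr, , drop = FALSE], y[tr],
                                  classes, seed = spec@seed + f)
            computeMetrics(.predictClassifier(fit, X[!tr, , drop = FALSE]),
                           y[!tr])["weighted_f1"]
        }, numeric(1))
        mean(scores)
    }
    trace <- vector("list", iterations)
    scores <- numeric(iterations)
    nInit <- max(2L, min(10L, iterations))
    for (it in seq_len(iterations)) {
        params <- if (it == 1L) spec@hyperparameters
        else if (method == "random" || it <= nInit) .sampleParams(spec@kind)
        else {
            ## surrogate proposal over a pool of random candidates
            enc <- do.call(rbind, lapply(trace[seq_len(it - 1L)],
                                         .encodeParams))
            sur <- ranger::ranger(
                x = as.data.frame(enc), y = scores[seq_len(it - 1L)],
                num.trees = 100L, seed = spec@seed, num.threads = 1L)
            pool <- lapply(seq_len(20L), function(j) .sampleParams(spec@kind))
            penc <- as.data.frame(do.call(rbind, lapply(pool,
                                                        .encodeParams)))
            pred <- stats::predict(sur, data = penc)$predictions
            pool[[which.max(pred)]]
        }
        trace[[it]] <- params
        scores[it] <- evalParams(params)
    }
    best <- trace[[which.max(scores)]]
    out <- classifierSpec(spec@kind, best, spec@classWeightBalanced,
                          spec@seed)
    attr(out, "tuning") <- list(params = trace, scores = scores,
                                method = method, folds = folds)
    out
}

#' Recursive feature elimination with step size 1
#'
#' Iteratively fits the classifier on the remaining features, removes the
#' single lowest-importance feature (ties: the lexicographically greatest
#' key is removed first), and repeats until one feature remains. The
#' classifier's hyperparameters are held constant throughout.
#'
#' @param spec a tuned \code{\linkS4class{ClassifierSpec}}.
#' @param x an \code{\linkS4class{SSRFeatureSet}}.
#' @param features feature keys to rank (default: all in \code{x}).
#' @return Character vector of feature keys in reverse elimination order:
#'   the last-surviving (most important) feature first.
#' @export
rfeRank <- function(spec, x, features = NULL) {
    if (is.null(features)) features <- featureKeys(x)
    X <- t(presenceMatrix(x[features, ]))
    y <- as.character(sampleGroups(x))
    classes <- unique(y)
    eliminated <- character(0)
    remaining <- features
    while (length(remaining) > 1L) {
        fit <- .fitClassifier(spec, X[, remaining, drop = FALSE], y,
                              classes, seed = spec@seed)
        imp <- .importanceClassifier(fit)[remaining]
        drop <- remaining[order(imp, remaining, method = "radix",
                                decreasing = c(FALSE, TRUE))][1]
        eliminated <- c(eliminated, drop)
        remaining <- setdiff(remaining, drop)
    }
    rev(c(eliminated, remaining))
}

#' Leave-one-out cross-validated evaluation
#'
#' Fits exactly n models, each predicting its single held-out sample, and
#' pools the n predictions into one metric set and confusion matrix.
#'
#' @param spec a \code{\linkS4class{ClassifierSpec}}.
#' @param x an \code{\linkS4class{SSRFeatureSet}}.
#' @param features feature keys to use (default: all).
#' @param replicate_seed seed for this replicate's model randomness.
#' @return list: \code{predictions} (named character), \code{metrics}
#'   (see \code{\link{computeMetrics}}), \code{confusion} (true classes in
#'   rows), \code{n_fits}.
#' @export
loocvEvaluate <- function(spec, x, features = NULL,
                          replicate_seed = spec@seed) {
    if (is.null(features)) features <- featureKeys(x)
    X <- t(presenceMatrix(x[features, ]))
    y <- as.character(sampleGroups(x))
    classes <- unique(y)
    n <- nrow(X)
    if (n < 2) stop("at least two samples required")
    before <- fitCount()
    preds <- vapply(seq_len(n), function(i) {
        fit <- .fitClassifier(spec, X[-i, , drop = FALSE], y[-i], classes,
                              seed = replicate_seed)
        .predictClassifier(fit, X[i, , drop = FALSE])
    }, "")
    names(preds) <- rownames(X)
    list(predictions = preds, metrics = computeMetrics(preds, y),
         confusion = .confusion(preds, y, classes),
         n_fits = fitCount() - before)
}

#' Build a LOOCV learning curve along a feature ranking
#'
#' For every k from 1 to \code{k_max}, evaluates the top-k ranked features
#' with \code{\link{loocvEvaluate}} across \code{replicates} replicates
#' (replicate r uses seed \code{base_seed + r}), storing mean and SD of
#' the four metrics per k, the per-k replicate-averaged confusion
#' matrices, and the confusion matrix averaged over all replicates and k.
#'
#' @param spec a \code{\linkS4class{ClassifierSpec}}.
#' @param ranking feature keys, best first (see \code{\link{rfeRank}}).
#' @param x an \code{\linkS4class{SSRFeatureSet}}.
#' @param k_max largest prefix length (default 30, capped at the ranking
#'   length).
#' @param replicates replicates per k (default 30).
#' @param base_seed base seed; replicate r uses \code{base_seed + r}.
#' @return An \code{\linkS4class{SSRLearningCurve}}.
#' @export
learningCurve <- function(spec, ranking, x, k_max = 30L, replicates = 30L,
                          base_seed = spec@seed) {
    stopifnot(length(ranking) >= 1L)
    k_max <- min(as.integer(k_max), length(ranking))
    metricNames <- c("weighted_f1", "accuracy", "weighted_precision",
                     "weighted_recall")
    means <- sds <- matrix(NA_real_, k_max, 4L,
                           dimnames = list(NULL, metricNames))
    classes <- unique(as.character(sampleGroups(x)))
    K <- length(classes)
    confByK <- vector("list", k_max)
    total <- matrix(0, K, K, dimnames = list(classes, classes))
    for (k in seq_len(k_max)) {
        vals <- matrix(NA_real_, replicates, 4L)
        confSum <- matrix(0, K, K, dimnames = list(classes, classes))
        for (r in seq_len(replicates)) {
            ev <- loocvEvaluate(spec, x, features = ranking[seq_len(k)],
                                replicate_seed = base_seed + r)
            vals[r, ] <- ev$metrics[metricNames]
            confSum <- confSum + unclass(ev$confusion)
        }
        means[k, ] <- colMeans(vals)
        sds[k, ] <- apply(vals, 2, stats::sd)
        confByK[[k]] <- confSum / replicates
        total <- total + confSum
    }
    methods::new("SSRLearningCurve", k = seq_len(k_max), means = means,
                 sds = sds,
                 featuresAtK = lapply(seq_len(k_max),
                                      function(k) ranking[seq_len(k)]),
                 confusionByK = confByK,
                 meanConfusion = total / (replicates * k_max),
                 replicates = as.integer(replicates))
}

#' Pick the best point of a learning curve
#'
#' Trades maximum score against panel size: returns the smallest k whose
#' mean weighted F1 exactly equals the curve maximum.
#'
#' @param curve an \code{\linkS4class{SSRLearningCurve}}.
#' @return list with \code{best_k} and \code{best_features}.
#' @export
chooseBest <- function(curve) {
    f1 <- curve@means[, "weighted_f1"]
    best_k <- which(f1 == max(f1))[1]
    list(best_k = as.integer(best_k),
         best_features = curve@featuresAtK[[best_k]])
}

#' Default benchmark configuration
#'
#' @param tune_iterations,tune_folds hyperparameter search budget.
#' @param tune_method \code{"smbo"} or \code{"random"}.
#' @param replicates,k_max learning-curve settings.
#' @param base_seed seed from which all per-combination seeds derive.
#' @return list of settings for \code{\link{runBenchmark}}.
#' @export
benchConfig <- function(tune_iterations = 100L, tune_folds = 3L,
                        tune_method = "smbo", replicates = 30L,
                        k_max = 30L, base_seed = 1L) {
    list(tune_iterations = as.integer(tune_iterations),
         tune_folds = as.integer(tune_folds), tune_method = tune_method,
         replicates = as.integer(replicates), k_max = as.integer(k_max),
         base_seed = as.integer(base_seed))
}

#' Benchmark every (selection, classifier) combination
#'
#' For each pair: tunes the classifier on the selection's features, ranks
#' them by step-1 recursive feature elimination with the tuned
#' hyperparameters held fixed, builds the LOOCV learning curve over
#' replicates, picks the best k, and records feature importances from a
#' full-data fit at the best k. Per-combination failures are recorded and
#' do not abort the run.
#'
#' @param x an \code{\linkS4class{SSRFeatureSet}}.
#' @param selections list of \code{\linkS4class{SSRSelection}} objects.
#' @param classifiers list of \code{\linkS4class{ClassifierSpec}} objects.
#' @param config see \code{\link{benchConfig}}.
#' @return list of class \code{"ssr_bench"}: \code{results} (named list of
#'   \code{\linkS4class{SSRBenchResult}}), \code{summary} (a data.frame
#'   shaped like published benchmark tables: method, classifier, SSRs
#'   incorporated, mean and SD of the four metrics at the best k) and
#'   \code{failures}.
#' @export
runBenchmark <- function(x, selections, classifiers,
                         config = benchConfig()) {
    stopifnot(length(selections) > 0)
    results <- list()
    failures <- list()
    for (sel in selections) {
        for (spec in classifiers) {
            id <- paste(sel@method, spec@kind, sep = " x ")
            res <- tryCatch({
                feats <- sel@features
                if (!length(feats)) stop("empty selection")
                tuned <- tuneClassifier(spec, x, features = feats,
                                        iterations = config$tune_iterations,
                                        folds = config$tune_folds,
                                        method = config$tune_method)
                ranking <- rfeRank(tuned, x, features = feats)
                curve <- learningCurve(tuned, ranking, x,
                                       k_max = config$k_max,
                                       replicates = config$replicates,
                                       base_seed = config$base_seed)
                best <- chooseBest(curve)
                fullFit <- .fitClassifier(
                    tuned, t(presenceMatrix(x[best$best_features, ])),
                    as.character(sampleGroups(x)),
                    unique(as.character(sampleGroups(x))),
                    seed = config$base_seed)
                methods::new("SSRBenchResult", curve = curve,
                             bestK = best$best_k,
                             bestFeatures = best$best_features,
                             meanConfusion = curve@meanConfusion,
                             importances = .importanceClassifier(fullFit),
                             selectionMethod = sel@method,
                             classifierKind = spec@kind)
            }, error = function(e) e)
            if (inherits(res, "error")) failures[[id]] <- conditionMessage(res)
            else results[[id]] <- res
        }
    }
    structure(list(results = results, summary = benchSummary(results),
                   failures = failures),
              class = "ssr_bench")
}

#' Summarise benchmark results as a metrics table
#'
#' @param results named list of \code{\linkS4class{SSRBenchResult}}.
#' @return data.frame with one row per combination: selection method,
#'   classifier, SSRs incorporated, and mean/SD of weighted F1, accuracy,
#'   weighted precision and weighted recall at the chosen k.
#' @export
benchSummary <- function(results) {
    if (!length(results))
        return(data.frame(method = character(), classifier = character()))
    rows <- lapply(results, function(r) {
        k <- r@bestK
        data.frame(method = r@selectionMethod,
                   classifier = r@classifierKind, ssrs_incorporated = k,
                   mean_f1 = r@curve@means[k, "weighted_f1"],
                   sd_f1 = r@curve@sds[k, "weighted_f1"],
                   mean_acc = r@curve@means[k, "accuracy"],
                   sd_acc = r@curve@sds[k, "accuracy"],
                   mean_prec = r@curve@means[k, "weighted_precision"],
                   sd_prec = r@curve@sds[k, "weighted_precision"],
                   mean_rec = r@curve@means[k, "weighted_recall"],
                   sd_rec = r@curve@sds[k, "weighted_recall"],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
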