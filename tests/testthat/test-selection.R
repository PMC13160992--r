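test_that("gcSSRSelect retains exactly the group-conserved features", {
    m <- matrix(0L, 4, 6, dimnames = list(
        c("L1|AG|5", "L2|TC|6", "L3|TCA|4", "L4|A|10"),
        c("a1", "a2", "a3", "b1", "b2", "b3")))
    groups <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
    m["L1|AG|5", ] <- 1L                      # conserved in both groups
    m["L2|TC|6", c("a1", "a2", "a3")] <- 1L   # conserved in A only
    m["L3|TCA|4", c("a1", "a2", "b1")] <- 1L  # conserved nowhere
    m["L4|A|10", c("b1", "b2", "b3", "a1")] <- 1L  # conserved in B
    sel <- gcSSRSelect(SSRFeatureSet(m, groups))
    expect_s4_class(sel, "SSRSelection")
    expect_equal(selectionMethod(sel), "gc_ssr")
    expect_setequal(selectedFeatures(sel),
                    c("L1|AG|5", "L2|TC|6", "L4|A|10"))
    ## ordered by group count desc, then key
    expect_equal(selectedFeatures(sel)[1], "L1|AG|5")
    expect_equal(unname(selectionScores(sel)), c(2, 1, 1))
    ga <- groupAttribution(sel)
    expect_setequal(ga[["L1|AG|5"]], c("A", "B"))
    expect_equal(ga[["L2|TC|6"]], "A")
    expect_equal(ga[["L4|A|10"]], "B")
})

test_that("gcSSRSelect matches the exhaustive oracle on random tables", {
    set.seed(19)
    for (rep in 1:25) {
        n <- sample(6:15, 1)
        f <- sample(20:60, 1)
        groups <- sort(sample(c("A", "B", "C"), n, replace = TRUE))
        if (length(unique(groups)) < 2) next
        ids <- paste0("s", seq_len(n))
        names(groups) <- ids
        m <- matrix(rbinom(f * n, 1, 0.5), f, n,
                    dimnames = list(sprintf("L%03d|AG|%d", seq_len(f),
                                            5L + seq_len(f) %% 6L), ids))
        fs <- SSRFeatureSet(m, groups)
        got <- selectedFeatures(gcSSRSelect(fs))
        expect_setequal(got, oracleGC(m, groups))
        ## permutation invariance over sample order
        perm <- sample(ids)
        got2 <- selectedFeatures(gcSSRSelect(SSRFeatureSet(
            m[, perm], groups[perm])))
        expect_identical(got, got2)
    }
})

test_that("anovaFScores matches the textbook oracle and edge cases", {
    set.seed(23)
    groups <- c(rep("A", 5), rep("B", 4), rep("C", 6))
    ids <- paste0("s", seq_along(groups))
    names(groups) <- ids
    m <- matrix(rbinom(40 * 15, 1, 0.4), 40, 15,
                dimnames = list(sprintf("L%02d|AG|5", 1:40), ids))
    ## perfect indicator of group A and a constant feature
    m[1, ] <- as.integer(groups == "A")
    m[2, ] <- 1L
    fs <- SSRFeatureSet(m, groups)
    f <- anovaFScores(fs)
    expect_identical(unname(f[1]), Inf)
    expect_identical(unname(f[2]), 0)
    for (i in 3:40)
        expect_equal(unname(f[i]), oracleF(m[i, ], groups),
                     tolerance = 1e-10)
    ## cross-check finite values against stats::aov
    for (i in c(5, 17, 33)) {
        if (!is.finite(f[i])) next
        av <- summary(stats::aov(m[i, ] ~ factor(groups)))[[1]]
        expect_equal(unname(f[i]), av[["F value"]][1], tolerance = 1e-8)
    }
})

test_that("selectKBest ranks by F with lexicographic ties", {
    groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
    m <- matrix(c(1L, 1L, 0L, 0L,   # perfect, Inf
                  0L, 0L, 1L, 1L,   # perfect, Inf
                  1L, 0L, 1L, 0L,   # useless
                  1L, 1L, 1L, 1L),  # constant
                4, 4, byrow = TRUE,
                dimnames = list(c("L2|AG|5", "L1|AG|5", "L3|AG|5",
                                  "L4|AG|5"),
                                names(groups)))
    sel <- selectKBest(SSRFeatureSet(m, groups), k = 2)
    ## both Inf: lexicographic tie-break puts L1 before L2
    expect_equal(selectedFeatures(sel), c("L1|AG|5", "L2|AG|5"))
    selAll <- selectKBest(SSRFeatureSet(m, groups), k = 99)
    expect_equal(length(selectedFeatures(selAll)), 4L)
    ## monotone prefix property: top-k is a prefix of top-(k+1)
    for (k in 1:3) {
        a <- selectedFeatures(selectKBest(SSRFeatureSet(m, groups), k))
        b <- selectedFeatures(selectKBest(SSRFeatureSet(m, groups), k + 1))
        expect_identical(a, b[seq_along(a)])
    }
    expect_error(selectKBest(SSRFeatureSet(m, groups), k = 0), "k")
})

test_that("hybridSelect recovers planted features and is deterministic", {
    cfg <- simulationConfig(samples_per_group = c(A = 6L, B = 6L, C = 6L),
                            n_conserved_per_group = c(A = 2L, B = 2L,
                                                      C = 1L),
                            n_loci = 60L, n_noise_features = 50L,
                            noise_presence_prob = 0.15,
                            heterogeneous_groups = character(0), seed = 13)
    sim <- simulateFeatureTable(cfg)
    planted <- unlist(sim$truth$planted_conserved)
    sel <- hybridSelect(sim$features, k1 = 40L, k2 = 5L,
                        search_iterations = 8L, folds = 3L, seed = 3L)
    expect_equal(length(selectedFeatures(sel)), 5L)
    expect_setequal(selectedFeatures(sel), planted)
    sel2 <- hybridSelect(sim$features, k1 = 40L, k2 = 5L,
                         search_iterations = 8L, folds = 3L, seed = 3L)
    expect_identical(selectedFeatures(sel), selectedFeatures(sel2))
    expect_identical(selectionScores(sel), selectionScores(sel2))
    expect_error(hybridSelect(sim$features, k1 = 3L, k2 = 5L), "k2")
})

test_that("lassoFit separates planted structure and stores the search", {
    sim <- simulateFeatureTable(separableConfig(seed = 29, noise = 0.1))
    model <- lassoFit(sim$features, search_iterations = 8L, seed = 2L)
    expect_s4_class(model, "LassoModel")
    expect_setequal(model@classes, c("A", "B", "C"))
    expect_equal(length(model@tuning$candidates), 8L)
    expect_true(all(diff(model@tuning$candidates) >= 0))
    expect_true(max(model@tuning$weighted_f1) == 1)
    ## full-data refit predicts the training labels perfectly
    p <- predictProba(model, sim$features)
    expect_equal(unname(rowSums(p)), rep(1, ncol(sim$features)),
                 tolerance = 1e-12)
    pred <- model@classes[max.col(p)]
    expect_equal(pred, unname(as.character(sampleGroups(sim$features))))
})

test_that("extreme regularisation zeroes all weights and predictProba is uniform", {
    sim <- simulateFeatureTable(separableConfig(seed = 31))
    model <- lassoFit(sim$features, c_range = c(1e-9, 2e-9),
                      search_iterations = 3L, seed = 1L)
    expect_true(all(model@weights == 0))
    p <- predictProba(model, sim$features)
    ## all-zero weights: every sample gets the same (intercept-only)
    ## probability vector, and rows still sum to one
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-12)
    for (i in seq_len(nrow(p)))
        expect_equal(unname(p[i, ]), unname(p[1, ]), tolerance = 1e-12)
    expect_warning(lassoSelect(sim$features, c_range = c(1e-9, 2e-9),
                               search_iterations = 3L, seed = 1L),
                   "empty")
})

test_that("lassoLoss matches the explicit double-sum oracle", {
    set.seed(37)
    classes <- c("A", "B", "C")
    X <- matrix(rbinom(12 * 7, 1, 0.5), 12, 7,
                dimnames = list(paste0("s", 1:12),
                                sprintf("L%d|AG|5", 1:7)))
    y <- sample(classes, 12, replace = TRUE)
    for (rep in 1:5) {
        W <- matrix(rnorm(3 * 7), 3, 7,
                    dimnames = list(classes, colnames(X)))
        b <- rnorm(3)
        lam <- runif(1, 0, 0.5)
        model <- methods::new("LassoModel", weights = W, intercepts = b,
                              lambda = lam, classes = classes,
                              featureOrder = colnames(X))
        expect_equal(lassoLoss(model, X, labels = y),
                     oracleLassoLoss(W, b, X, y, classes, lam),
                     tolerance = 1e-12)
    }
    ## loss is monotone in lambda for fixed weights
    W <- matrix(rnorm(3 * 7), 3, 7, dimnames = list(classes, colnames(X)))
    b <- rnorm(3)
    losses <- vapply(c(0, 0.1, 0.5, 2), function(l) {
        m <- methods::new("LassoModel", weights = W, intercepts = b,
                          lambda = l, classes = classes,
                          featureOrder = colnames(X))
        lassoLoss(m, X, labels = y)
    }, numeric(1))
    expect_true(all(diff(losses) > 0))
    ## uniform probabilities give cross-entropy log(K) at lambda 0
    m0 <- methods::new("LassoModel",
                       weights = matrix(0, 3, 7,
                                        dimnames = list(classes,
                                                        colnames(X))),
                       intercepts = rep(0, 3), lambda = 0,
                       classes = classes, featureOrder = colnames(X))
    expect_equal(lassoLoss(m0, X, labels = y), log(3), tolerance = 1e-12)
})

test_that("lassoSelect returns planted features under the cap", {
    sim <- simulateFeatureTable(separableConfig(seed = 43, noise = 0.1))
    planted <- unlist(sim$truth$planted_conserved)
    sel <- lassoSelect(sim$features, cap = 9L, search_iterations = 8L,
                       seed = 2L)
    expect_equal(selectionMethod(sel), "lasso")
    expect_lte(length(selectedFeatures(sel)), 9L)
    ## the L1 penalty is sparse: every retained feature is a planted
    ## marker, and each group keeps at least one of its own markers
    expect_true(all(selectedFeatures(sel) %in% planted))
    for (g in names(sim$truth$planted_conserved))
        expect_gte(length(intersect(selectedFeatures(sel),
                                    sim$truth$planted_conserved[[g]])), 1L)
    ## scores are the max |coefficient| and are non-increasing
    expect_true(all(diff(selectionScores(sel)) <= 1e-12))
})
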