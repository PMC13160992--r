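# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Exhaustive SSR scanner: for every unit length and every position that
# starts a maximal periodic region (the base one before does not continue
# the period), count full unit copies greedily.
oracleDetect <- function(seq, thresholds = defaultThresholds()) {
    n <- nchar(seq)
    chars <- strsplit(seq, "")[[1]]
    isN <- chars == "N"
    out <- list()
    for (u in 1:6) {
        if (n < u * thresholds[u]) next
        for (start in seq_len(n - u + 1L)) {
            motif <- substr(seq, start, start + u - 1L)
            if (grepl("N", motif, fixed = TRUE)) next
            # region start: position start-1 must not continue the period
            if (start > 1L && !isN[start - 1L] &&
                chars[start - 1L] == chars[start - 1L + u]) next
            copies <- 1L
            repeat {
                nxt <- start + copies * u
                if (nxt + u - 1L > n) break
                if (substr(seq, nxt, nxt + u - 1L) != motif) break
                copies <- copies + 1L
            }
            if (copies < thresholds[u]) next
            # primitivity
            prim <- TRUE
            for (d in seq_len(u - 1L)) {
                if (u %% d != 0L) next
                if (motif == strrep(substr(motif, 1L, d), u / d)) {
                    prim <- FALSE
                    break
                }
            }
            if (!prim) next
            out[[length(out) + 1L]] <- data.frame(
                start = start - 1L, end = start - 1L + u * copies,
                motif = motif, repeat_count = copies,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(start = integer(), end = integer(),
                          motif = character(), repeat_count = integer()))
    df <- do.call(rbind, out)
    df[order(df$start, df$end), , drop = FALSE]
}

# Exhaustive group-wise conserved filter: double loop over features and
# groups.
oracleGC <- function(m, groups) {
    retained <- character(0)
    for (f in rownames(m)) {
        for (g in unique(groups)) {
            if (all(m[f, names(groups)[groups == g]] == 1)) {
                retained <- c(retained, f)
                break
            }
        }
    }
    retained
}

# Textbook two-loop one-way ANOVA F for one feature vector.
oracleF <- function(v, groups) {
    K <- length(unique(groups))
    n <- length(v)
    grand <- mean(v)
    ssb <- 0
    ssw <- 0
    for (g in unique(groups)) {
        vg <- v[groups == g]
        ssb <- ssb + length(vg) * (mean(vg) - grand)^2
        ssw <- ssw + sum((vg - mean(vg))^2)
    }
    if (ssw == 0 && ssb == 0) return(0)
    if (ssw == 0) return(Inf)
    (ssb / (K - 1)) / (ssw / (n - K))
}

# Explicit double-sum evaluation of the combined cross-entropy + L1 loss,
# with probabilities recomputed from first principles.
oracleLassoLoss <- function(W, b, X, y, classes, lambda) {
    n <- nrow(X)
    total <- 0
    for (i in seq_len(n)) {
        raw <- numeric(length(classes))
        for (k in seq_along(classes))
            raw[k] <- 1 / (1 + exp(-(sum(W[k, ] * X[i, ]) + b[k])))
        p <- raw / sum(raw)
        for (k in seq_along(classes))
            if (y[i] == classes[k])
                total <- total - log(max(p[k], 1e-15))
    }
    l1 <- 0
    for (k in seq_len(nrow(W)))
        for (j in seq_len(ncol(W)))
            l1 <- l1 + abs(W[k, j])
    total / n + lambda * l1
}

# Set-based Jaccard distance matrix.
oracleJaccard <- function(m) {
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            A <- which(m[i, ] == 1)
            B <- which(m[j, ] == 1)
            un <- length(union(A, B))
            d[i, j] <- if (un == 0) 0 else 1 - length(intersect(A, B)) / un
        }
    }
    d
}

# Random ultrametric distance matrix built from an explicit random
# agglomeration with strictly increasing merge heights.
randomUltrametric <- function(n, seed) {
    set.seed(seed)
    labels <- paste0("s", seq_len(n))
    clusters <- as.list(labels)
    d <- matrix(0, n, n, dimnames = list(labels, labels))
    h <- 0
    while (length(clusters) > 1L) {
        h <- h + runif(1, 0.5, 2)
        pick <- sample(length(clusters), 2L)
        a <- clusters[[pick[1]]]
        b <- clusters[[pick[2]]]
        d[a, b] <- h
        d[b, a] <- h
        clusters <- c(clusters[-pick], list(c(a, b)))
    }
    d
}

# Independent re-implementation of the same-motif merge and compound rules,
# written as a plain scan over a sorted call table.
oracleClassify <- function(calls, interrupt_max_bp = 4L,
                           compound_gap_bp = 10L) {
    calls <- calls[order(calls$sample_id, calls$seq_id, calls$start), ]
    res <- list()
    i <- 1L
    while (i <= nrow(calls)) {
        cur <- calls[i, ]
        j <- i + 1L
        while (j <= nrow(calls) &&
               calls$sample_id[j] == cur$sample_id &&
               calls$seq_id[j] == cur$seq_id &&
               calls$motif[j] == cur$motif &&
               calls$start[j] - cur$end <= interrupt_max_bp) {
            cur$end <- calls$end[j]
            cur$repeat_count <- cur$repeat_count + calls$repeat_count[j]
            cur$ssr_class <- "imperfect"
            j <- j + 1L
        }
        res[[length(res) + 1L]] <- cur
        i <- j
    }
    out <- do.call(rbind, res)
    if (nrow(out) > 1L) {
        for (i in seq_len(nrow(out) - 1L)) {
            same <- out$sample_id[i + 1L] == out$sample_id[i] &&
                out$seq_id[i + 1L] == out$seq_id[i]
            if (same && out$motif[i + 1L] != out$motif[i] &&
                out$start[i + 1L] - out$end[i] <= compound_gap_bp)
                out$ssr_class[c(i, i + 1L)] <- "compound"
        }
    }
    rownames(out) <- NULL
    out
}

# Plant arrays (with period-breaking flanks) into a repeat-free background
# and return both the sequence and the expected call table.
plantArrays <- function(len, arrays, seed) {
    set.seed(seed)
    bg <- ssrOrigin:::.scrubbedBackground(len, defaultThresholds())
    used <- integer(0)
    expected <- list()
    for (a in arrays) {
        arr <- strrep(a$motif, a$count)
        w <- nchar(arr)
        repeat {
            pos <- sample(2L:(len - w - 1L), 1L)  # 1-based array start
            if (!any(abs(pos - used) < w + 220L)) break
        }
        used <- c(used, pos)
        u <- nchar(a$motif)
        left <- setdiff(c("A", "C", "G", "T"), substr(a$motif, u, u))[1]
        right <- setdiff(c("A", "C", "G", "T"), substr(a$motif, 1, 1))[1]
        substr(bg, pos - 1L, pos - 1L) <- left
        substr(bg, pos, pos + w - 1L) <- arr
        substr(bg, pos + w, pos + w) <- right
        expected[[length(expected) + 1L]] <- data.frame(
            start = pos - 1L, end = pos - 1L + w, motif = a$motif,
            repeat_count = a$count, stringsAsFactors = FALSE)
    }
    list(seq = bg, expected = do.call(rbind, expected))
}

# Small separable feature-table configuration reused across tests.
separableConfig <- function(seed, noise = 0, n_noise = 15L) {
    simulationConfig(samples_per_group = c(A = 6L, B = 5L, C = 5L),
                     n_conserved_per_group = c(A = 3L, B = 3L, C = 3L),
                     n_loci = 30L, n_noise_features = n_noise,
                     noise_presence_prob = noise,
                     heterogeneous_groups = character(0), seed = seed)
}

randomSequence <- function(n, allowN = FALSE) {
    alphabet <- c("A", "C", "G", "T", if (allowN) "N")
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
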