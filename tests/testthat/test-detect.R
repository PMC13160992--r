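test_that("detectSSRs finds constructed perfect repeats with exact spans", {
    calls <- detectSSRs(c(chr1 = "TCATCATCATCATCA"))
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$motif, "TCA")
    expect_equal(calls$repeat_count, 5L)
    expect_equal(calls$start, 0L)
    expect_equal(calls$end, 15L)
    expect_equal(calls$ssr_class, "perfect")

    ## embedded periodic region: GG|AGAGAGAGAGA|TT contains a maximal
    ## period-2 region starting at offset 1 (G A G A ... = (GA)6); the
    ## motif is reported as it appears at the region start and the
    ## partial trailing unit is excluded
    calls <- detectSSRs(c(c1 = "GGAGAGAGAGAGATT"))
    expect_equal(calls$motif, "GA")
    expect_equal(calls$repeat_count, 6L)
    expect_equal(calls$start, 1L)
    expect_equal(calls$end, 13L)
})

test_that("thresholds are applied per unit length", {
    thr <- defaultThresholds()
    expect_identical(unname(thr), c(10L, 5L, 4L, 3L, 3L, 3L))
    ## (AG)4 below the di threshold, (AG)5 at it
    expect_equal(nrow(detectSSRs(c(s = "TTAGAGAGAGTT"))), 0L)
    expect_equal(nrow(detectSSRs(c(s = "TTAGAGAGAGAGTT"))), 1L)
    ## (A)9 below mono threshold, (A)10 at it
    expect_equal(nrow(detectSSRs(c(s = strrep("A", 9)))), 0L)
    expect_equal(detectSSRs(c(s = strrep("A", 10)))$repeat_count, 10L)
})

test_that("non-primitive motifs are never reported", {
    ## (AT)10 must be one dinucleotide call, not (ATAT)5 or (A T)x anything
    calls <- detectSSRs(c(s = strrep("AT", 10)))
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$motif, "AT")
    expect_equal(calls$repeat_count, 10L)
    expect_true(isPrimitiveMotif("AT"))
    expect_false(isPrimitiveMotif("ATAT"))
    expect_false(isPrimitiveMotif("AAA"))
    expect_true(isPrimitiveMotif("ACG"))
    expect_false(isPrimitiveMotif("ACGACG"))
})

test_that("N never extends a run and invalid characters error", {
    ## (AG)5 N (AG)5: two separate perfect calls, no N inside either
    s <- paste0(strrep("AG", 5), "N", strrep("AG", 5))
    calls <- detectSSRs(c(s = s))
    expect_equal(nrow(calls), 2L)
    expect_true(all(!calls$contains_n))
    expect_error(detectSSRs(c(s = "ACGTX")), "invalid character")
})

test_that("detector matches the exhaustive oracle on random sequences", {
    set.seed(42)
    for (i in 1:60) {
        s <- randomSequence(sample(30:200, 1), allowN = i %% 5 == 0)
        ## bias towards repeats: sometimes paste in a short array
        if (i %% 2 == 0) {
            m <- c("A", "AG", "TCA", "AT")[sample(4, 1)]
            s <- paste0(s, strrep(m, sample(3:12, 1)), s)
        }
        got <- detectSSRs(c(x = s))[, c("start", "end", "motif",
                                        "repeat_count")]
        want <- oracleDetect(s)
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got, want, info = paste("seq", i))
    }
})

test_that("classifyCalls merges interrupted runs and marks compounds", {
    ## (AG)6 + 2 bp gap + (AG)5 -> one imperfect call with count 11
    s <- paste0("TT", strrep("AG", 6), "CC", strrep("AG", 5), "TT")
    calls <- detectSSRs(c(c1 = s), sample_id = "s1")
    out <- classifyCalls(calls)
    expect_equal(nrow(out), 1L)
    expect_equal(out$ssr_class, "imperfect")
    expect_equal(out$repeat_count, 11L)
    expect_equal(out$end - out$start, 2L + 12L + 10L)

    ## (AG)6 + 3 bp gap + (TC)5 -> both compound
    s <- paste0("TT", strrep("AG", 6), "AAA", strrep("TC", 5), "GG")
    out <- classifyCalls(detectSSRs(c(c1 = s), sample_id = "s1"))
    expect_equal(out$ssr_class, c("compound", "compound"))

    ## far apart: both stay perfect
    gap <- "CCCGGGCCCGG"  # 11 bp, repeat-free
    s <- paste0(strrep("AG", 6), gap, strrep("TC", 5))
    out <- classifyCalls(detectSSRs(c(c1 = s), sample_id = "s1"))
    expect_equal(out$ssr_class, c("perfect", "perfect"))
})

test_that("classifyCalls agrees with an independent re-implementation", {
    set.seed(7)
    for (rep in 1:20) {
        ## random synthetic call tables (no sequences needed)
        n <- sample(3:12, 1)
        motifs <- sample(c("AG", "TC", "TCA"), n, replace = TRUE)
        starts <- sort(sample(0:400, n))
        counts <- sample(5:9, n, replace = TRUE)
        calls <- data.frame(sample_id = "s1", seq_id = "c1",
                            start = starts,
                            end = starts + nchar(motifs) * counts,
                            motif = motifs, repeat_count = counts,
                            ssr_class = "perfect", contains_n = FALSE,
                            stringsAsFactors = FALSE)
        ## drop overlapping calls so the table is physically realisable
        keep <- c(TRUE, calls$start[-1] >= cummax(calls$end)[-n])
        calls <- calls[keep, , drop = FALSE]
        got <- classifyCalls(calls)
        want <- oracleClassify(calls)
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got[, c("start", "end", "motif", "repeat_count",
                             "ssr_class")],
                     want[, c("start", "end", "motif", "repeat_count",
                              "ssr_class")])
    }
})

test_that("assignLoci picks maximal overlap with deterministic ties", {
    ann <- data.frame(locus_id = c("L1", "L2"), seq_id = "c1",
                      start = c(0L, 150L), end = c(200L, 400L),
                      is_coding = c(TRUE, FALSE), stringsAsFactors = FALSE)
    calls <- data.frame(sample_id = "s", seq_id = "c1",
                        start = c(10L, 160L, 120L, 500L),
                        end = c(30L, 190L, 180L, 520L),
                        motif = "AG", repeat_count = 10L,
                        ssr_class = "perfect", contains_n = FALSE,
                        stringsAsFactors = FALSE)
    out <- assignLoci(calls, ann)
    ## call 1 only in L1; call 2 inside both, fully within overlap zone ->
    ## tie on overlap, smaller start wins (L1); call 3: 40 bp in L1 vs
    ## 30 bp in L2 -> L1; call 4 overlaps nothing
    expect_equal(out$locus_id,
                 c("L1", "L1", "L1", "intergenic:c1:0"))
})

test_that("assignLoci matches a brute-force overlap maximiser", {
    set.seed(11)
    ann <- data.frame(locus_id = paste0("L", 1:8), seq_id = "c1",
                      start = seq(0L, 700L, by = 100L),
                      end = seq(0L, 700L, by = 100L) + sample(60:140, 8,
                                                              replace = TRUE),
                      is_coding = TRUE, stringsAsFactors = FALSE)
    starts <- sample(0:750, 40)
    calls <- data.frame(sample_id = "s", seq_id = "c1", start = starts,
                        end = starts + sample(10:80, 40, replace = TRUE),
                        motif = "AG", repeat_count = 10L,
                        ssr_class = "perfect", contains_n = FALSE,
                        stringsAsFactors = FALSE)
    got <- assignLoci(calls, ann)$locus_id
    want <- vapply(seq_len(nrow(calls)), function(i) {
        ov <- pmin(calls$end[i], ann$end) - pmax(calls$start[i], ann$start)
        if (all(ov <= 0))
            return(sprintf("intergenic:c1:%d", calls$start[i] %/% 10000L))
        cand <- which(ov == max(ov) & ov > 0)
        ann$locus_id[cand[which.min(ann$start[cand])]]
    }, "")
    expect_equal(got, want)
})

test_that("buildFeatureMatrix keys features by locus, motif and count", {
    ann <- data.frame(locus_id = "L1", seq_id = "c1", start = 0L,
                      end = 100L, is_coding = TRUE, stringsAsFactors = FALSE)
    mk <- function(count, n = FALSE)
        data.frame(sample_id = "x", seq_id = "c1", start = 10L,
                   end = 10L + 2L * count, motif = "AG",
                   repeat_count = count, ssr_class = "perfect",
                   contains_n = n, stringsAsFactors = FALSE)
    labels <- c(s1 = "A", s2 = "B")
    fs <- buildFeatureMatrix(list(s1 = mk(5L), s2 = mk(6L)), ann, labels)
    ## different repeat counts are different features
    expect_setequal(featureKeys(fs), c("L1|AG|5", "L1|AG|6"))
    expect_equal(unname(presenceMatrix(fs)["L1|AG|5", ]), c(1L, 0L))
    ## drop_n removes N-containing calls
    fs2 <- buildFeatureMatrix(list(s1 = mk(5L, n = TRUE), s2 = mk(6L)),
                              ann, labels)
    expect_equal(featureKeys(fs2), "L1|AG|6")
    ## unlabelled samples are an error that names the offender
    expect_error(buildFeatureMatrix(list(s1 = mk(5L), zz = mk(6L)), ann,
                                    labels), "unlabelled.*zz")
    ## the reference sample contributes nothing
    fs3 <- buildFeatureMatrix(list(reference = mk(4L), s1 = mk(5L),
                                   s2 = mk(6L)), ann, labels,
                              exclude_reference_sample = "reference")
    expect_false("L1|AG|4" %in% featureKeys(fs3))
    expect_setequal(colnames(fs3), c("s1", "s2"))
})

test_that("coding_only keeps coding loci and drops intergenic features", {
    ann <- data.frame(locus_id = c("L1", "L2"), seq_id = "c1",
                      start = c(0L, 200L), end = c(100L, 300L),
                      is_coding = c(TRUE, FALSE), stringsAsFactors = FALSE)
    calls <- data.frame(sample_id = "x", seq_id = "c1",
                        start = c(10L, 210L, 500L),
                        end = c(20L, 220L, 510L), motif = "AG",
                        repeat_count = 5L, ssr_class = "perfect",
                        contains_n = FALSE, stringsAsFactors = FALSE)
    labels <- c(s1 = "A")
    fs <- buildFeatureMatrix(list(s1 = calls), ann, labels,
                             coding_only = TRUE)
    expect_equal(featureKeys(fs), "L1|AG|5")
})

test_that("GFF3 round trip preserves loci and coding flags", {
    ann <- data.frame(locus_id = c("LOC700001", "LOC700002"),
                      seq_id = "chr1", start = c(100L, 600L),
                      end = c(500L, 1000L), is_coding = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
    path <- tempfile(fileext = ".gff3")
    ssrOrigin:::.writeGFF3(ann, path)
    back <- readLocusAnnotations(path)
    expect_equal(back[order(back$locus_id), ], ann[order(ann$locus_id), ],
                 ignore_attr = TRUE)
})
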