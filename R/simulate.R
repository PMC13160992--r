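#' Configuration for the synthetic SSR benchmark generator
#'
#' Describes a study with a fixed number of origin groups of unequal size,
#' a set of group-conserved SSR markers planted into every sample of their
#' group, and independent Bernoulli noise markers. Defaults mirror a
#' four-group design with groups PG (n=8), CO (n=4), MP (n=12) and FG
#' (n=14), where PG is heterogeneous (carries no group-wide conserved
#' marker) and the motif-length distribution is skewed towards dinucleotide
#' repeats.
#'
#' @param samples_per_group named integer vector: group -> sample count.
#' @param n_conserved_per_group named integer vector: group -> number of
#'   planted conserved markers (0 for heterogeneous groups).
#' @param n_loci number of annotated loci available to host features; must
#'   be at least the total number of features.
#' @param n_noise_features number of noise markers.
#' @param noise_presence_prob probability that a noise marker (or a planted
#'   marker outside its own group) is present in a given sample.
#' @param motif_length_weights 6 non-negative weights for motif lengths 1-6.
#' @param repeat_count_ranges list of 6 inclusive \code{c(lo, hi)} integer
#'   ranges, one per unit length; all at or above the detection thresholds.
#' @param heterogeneous_groups character vector of groups in which no marker
#'   may be conserved across all samples (enforced by rejection).
#' @param genome_mode emit FASTA/GFF3 sample sets rather than a table only.
#' @param locus_length length in bp of each simulated locus.
#' @param seed integer seed; all randomness flows from it.
#' @return A validated config list of class \code{"ssr_sim_config"}.
#' @export
simulationConfig <- function(samples_per_group = c(PG = 8L, CO = 4L,
                                                   MP = 12L, FG = 14L),
                             n_conserved_per_group = c(PG = 0L, CO = 8L,
                                                       MP = 6L, FG = 5L),
                             n_loci = 240L,
                             n_noise_features = 200L,
                             noise_presence_prob = 0.15,
                             motif_length_weights = c(0.20, 0.48, 0.17,
                                                      0.06, 0.05, 0.04),
                             repeat_count_ranges = list(c(10L, 21L),
                                 c(5L, 21L), c(4L, 6L), c(3L, 4L),
                                 c(3L, 3L), c(3L, 3L)),
                             heterogeneous_groups = "PG",
                             genome_mode = FALSE,
                             locus_length = 400L,
                             seed = 1L) {
    cfg <- list(n_groups = length(samples_per_group),
                samples_per_group = samples_per_group,
                n_conserved_per_group = n_conserved_per_group,
                n_loci = as.integer(n_loci),
                n_noise_features = as.integer(n_noise_features),
                noise_presence_prob = noise_presence_prob,
                motif_length_weights = motif_length_weights,
                repeat_count_ranges = repeat_count_ranges,
                heterogeneous_groups = heterogeneous_groups,
                genome_mode = isTRUE(genome_mode),
                locus_length = as.integer(locus_length),
                seed = as.integer(seed))
    .validateSimConfig(cfg)
    class(cfg) <- "ssr_sim_config"
    cfg
}

.simConfigError <- function(field, why)
    stop(sprintf("invalid simulation config: field '%s' %s", field, why),
         call. = FALSE)

.validateSimConfig <- function(cfg) {
    spg <- cfg$samples_per_group
    if (is.null(names(spg)) || any(names(spg) == ""))
        .simConfigError("samples_per_group", "must be a named vector")
    if (any(spg < 1)) .simConfigError("samples_per_group",
                                      "entries must be positive")
    ncg <- cfg$n_conserved_per_group
    if (!setequal(names(ncg), names(spg)))
        .simConfigError("n_conserved_per_group",
                        "must name the same groups as samples_per_group")
    if (any(ncg < 0)) .simConfigError("n_conserved_per_group",
                                      "entries must be non-negative")
    het <- cfg$heterogeneous_groups
    if (length(bad <- setdiff(het, names(spg))))
        .simConfigError("heterogeneous_groups",
                        paste("names unknown group(s):",
                              paste(bad, collapse = ", ")))
    if (any(ncg[het] != 0))
        .simConfigError("heterogeneous_groups",
                        "must have n_conserved_per_group == 0")
    if (cfg$noise_presence_prob < 0 || cfg$noise_presence_prob > 1)
        .simConfigError("noise_presence_prob", "must be in [0, 1]")
    w <- cfg$motif_length_weights
    if (length(w) != 6L || any(w < 0) || sum(w) <= 0)
        .simConfigError("motif_length_weights",
                        "must be 6 non-negative weights with positive sum")
    rr <- cfg$repeat_count_ranges
    if (length(rr) != 6L ||
        !all(vapply(rr, function(r) length(r) == 2 && r[1] <= r[2],
                    logical(1))))
        .simConfigError("repeat_count_ranges",
                        "must be 6 inclusive lo<=hi ranges")
    thr <- defaultThresholds()
    for (u in 1:6)
        if (rr[[u]][1] < thr[u])
            .simConfigError("repeat_count_ranges",
                sprintf("range for unit length %d starts below the detection threshold %d",
                        u, thr[u]))
    if (cfg$n_loci < 1) .simConfigError("n_loci", "must be positive")
    if (cfg$n_noise_features < 0)
        .simConfigError("n_noise_features", "must be non-negative")
    if (cfg$locus_length < 1)
        .simConfigError("locus_length", "must be positive")
    total <- sum(ncg) + cfg$n_noise_features
    if (total > cfg$n_loci)
        .simConfigError("n_loci",
            sprintf("must host all %d features (one locus each)", total))
    invisible(TRUE)
}

.randomPrimitiveMotif <- function(len) {
    repeat {
        m <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
        if (isPrimitiveMotif(m)) return(m)
    }
}

## Draw feature keys and the presence matrix shared by both generator modes.
.simulateCore <- function(cfg) {
    groups <- names(cfg$samples_per_group)
    sampleIds <- unlist(lapply(groups, function(g)
        sprintf("%s_%02d", g, seq_len(cfg$samples_per_group[[g]]))))
    sampleGroup <- stats::setNames(rep(groups, cfg$samples_per_group),
                                   sampleIds)
    nPlanted <- sum(cfg$n_conserved_per_group)
    nFeat <- nPlanted + cfg$n_noise_features
    ## one locus per feature; loci ids mimic RefSeq-style gene symbols
    loci <- sprintf("LOC%06d", 700000L + seq_len(nFeat))
    lens <- sample(1:6, nFeat, replace = TRUE,
                   prob = cfg$motif_length_weights)
    motifs <- vapply(lens, .randomPrimitiveMotif, "")
    counts <- vapply(lens, function(u) {
        r <- cfg$repeat_count_ranges[[u]]
        if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
    }, integer(1))
    keys <- makeFeatureKey(loci, motifs, counts)
    featGroup <- c(rep(groups, cfg$n_conserved_per_group),
                   rep(NA_character_, cfg$n_noise_features))
    p <- cfg$noise_presence_prob
    pres <- matrix(stats::rbinom(nFeat * length(sampleIds), 1L, p),
                   nrow = nFeat, ncol = length(sampleIds),
                   dimnames = list(keys, sampleIds))
    for (i in seq_len(nFeat))
        if (!is.na(featGroup[i]))
            pres[i, sampleGroup == featGroup[i]] <- 1L
    ## heterogeneous groups: reject columns conserved across the whole group
    for (g in cfg$heterogeneous_groups) {
        gs <- sampleIds[sampleGroup == g]
        if (length(gs) == 0L) next
        for (i in seq_len(nFeat)) {
            tries <- 0L
            while (all(pres[i, gs] == 1L)) {
                tries <- tries + 1L
                if (tries > 50L) {
                    pres[i, sample(gs, 1L)] <- 0L
                    break
                }
                pres[i, gs] <- stats::rbinom(length(gs), 1L, p)
            }
        }
    }
    planted <- lapply(stats::setNames(groups, groups), function(g)
        keys[!is.na(featGroup) & featGroup == g])
    truth <- list(planted_conserved = planted,
                  noise_features = keys[is.na(featGroup)])
    class(truth) <- "ssr_truth"
    list(presence = pres, labels = sampleGroup, truth = truth,
         feature = data.frame(locus_id = loci, motif = motifs,
                              repeat_count = counts, key = keys,
                              stringsAsFactors = FALSE))
}

#' Simulate a binary SSR feature table with planted group structure
#'
#' Planted conserved markers are present in every sample of their own group
#' and appear in each other sample independently with
#' \code{noise_presence_prob}; noise markers are independent Bernoulli
#' everywhere. Columns that would by chance be conserved across all samples
#' of a heterogeneous group are redrawn, so such groups never carry a
#' group-wide conserved marker. Deterministic given \code{config$seed}.
#'
#' @param config an \code{\link{simulationConfig}} object.
#' @return list with elements \code{features}
#'   (\code{\linkS4class{SSRFeatureSet}}), \code{labels} (named character)
#'   and \code{truth} (planted/noise feature keys per group).
#' @examples
#' sim <- simulateFeatureTable(simulationConfig(seed = 7))
#' sim$features
#' @export
simulateFeatureTable <- function(config) {
    stopifnot(inherits(config, "ssr_sim_config"))
    set.seed(config$seed)
    core <- .simulateCore(config)
    list(features = SSRFeatureSet(core$presence, core$labels),
         labels = core$labels, truth = core$truth)
}

## Generate a random background sequence free of threshold-meeting repeats
## (detected runs are broken by substituting one interior base, iterated).
.scrubbedBackground <- function(len, thresholds) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    for (iter in 1:25) {
        calls <- .scanSequence(s, thresholds)
        if (nrow(calls) == 0L) return(s)
        for (i in seq_len(nrow(calls))) {
            pos <- (calls$start[i] + calls$end[i]) %/% 2L + 1L
            old <- substr(s, pos, pos)
            substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                                  old), 1L)
        }
    }
    s
}

## pick a flank base that breaks periodic extension of the planted array
.breakBase <- function(avoid) sample(setdiff(c("A", "C", "G", "T"), avoid),
                                     1L)

#' Simulate consensus genomes realising a planted SSR feature table
#'
#' Builds one reference chromosome containing \code{n_loci} annotated
#' gene/CDS intervals over a repeat-free background, then derives each
#' sample sequence from the reference by writing the planted repeat array
#' into every locus where the simulated truth says the sample carries that
#' feature. All sequences share the reference coordinate frame and length,
#' so downstream detection and matrix construction recover the truth table
#' exactly. Flanking bases around each planted array are set so the array
#' can neither extend nor merge with its surroundings.
#'
#' @param config an \code{\link{simulationConfig}} with
#'   \code{genome_mode = TRUE}.
#' @param dir optional directory; when given, writes
#'   \code{reference.fasta}, \code{samples/<id>.fasta}, \code{loci.gff3},
#'   \code{labels.csv} and \code{truth.json} there.
#' @return list with \code{reference} (named character of length 1),
#'   \code{samples} (named character vector of sample sequences),
#'   \code{annotations} (locus data.frame as in
#'   \code{\link{readLocusAnnotations}}), \code{labels} and \code{truth}.
#' @export
simulateGenomes <- function(config, dir = NULL) {
    stopifnot(inherits(config, "ssr_sim_config"))
    if (!config$genome_mode)
        .simConfigError("genome_mode", "must be TRUE for simulateGenomes")
    maxArray <- max(vapply(1:6, function(u)
        u * config$repeat_count_ranges[[u]][2], integer(1)))
    if (config$locus_length < maxArray + 4L)
        .simConfigError("locus_length",
            sprintf("too small to host the longest planted array (%d bp plus flanks)",
                    maxArray))
    set.seed(config$seed)
    core <- .simulateCore(config)
    thr <- defaultThresholds()
    spacer <- 100L
    nLoci <- config$n_loci
    L <- config$locus_length
    locusStart0 <- spacer + (seq_len(nLoci) - 1L) * (L + spacer)  # 0-based
    genomeLen <- nLoci * (L + spacer) + spacer
    ref <- .scrubbedBackground(genomeLen, thr)
    nFeat <- nrow(core$feature)
    ## feature i lives in locus i, array centred inside the locus
    arrLen <- nchar(core$feature$motif) * core$feature$repeat_count
    arrStart0 <- locusStart0[seq_len(nFeat)] + (L - arrLen) %/% 2L
    arrays <- vapply(seq_len(nFeat), function(i) {
        m <- core$feature$motif[i]
        paste(rep(m, core$feature$repeat_count[i]), collapse = "")
    }, "")
    leftFlank <- vapply(seq_len(nFeat), function(i) {
        m <- core$feature$motif[i]
        .breakBase(substr(m, nchar(m), nchar(m)))
    }, "")
    rightFlank <- vapply(seq_len(nFeat), function(i)
        .breakBase(substr(core$feature$motif[i], 1L, 1L)), "")
    samples <- vapply(colnames(core$presence), function(s) {
        g <- ref
        for (i in which(core$presence[, s] == 1L)) {
            a <- arrStart0[i]
            substr(g, a, a) <- leftFlank[i]          # pos a = 1-based a
            substr(g, a + 1L, a + arrLen[i]) <- arrays[i]
            substr(g, a + arrLen[i] + 1L, a + arrLen[i] + 1L) <- rightFlank[i]
        }
        g
    }, "")
    annotations <- data.frame(
        locus_id = sprintf("LOC%06d", 700000L + seq_len(nLoci)),
        seq_id = "chr1", start = locusStart0, end = locusStart0 + L,
        is_coding = TRUE, stringsAsFactors = FALSE)
    out <- list(reference = c(reference = ref), samples = samples,
                annotations = annotations, labels = core$labels,
                truth = core$truth,
                presence = SSRFeatureSet(core$presence, core$labels))
    if (!is.null(dir)) {
        dir.create(file.path(dir, "samples"), recursive = TRUE,
                   showWarnings = FALSE)
        Biostrings::writeXStringSet(
            Biostrings::DNAStringSet(c(chr1 = ref)),
            file.path(dir, "reference.fasta"))
        for (s in names(samples))
            Biostrings::writeXStringSet(
                Biostrings::DNAStringSet(stats::setNames(samples[s], "chr1")),
                file.path(dir, "samples", paste0(s, ".fasta")))
        .writeGFF3(annotations, file.path(dir, "loci.gff3"))
        writeLabelsCSV(core$labels, file.path(dir, "labels.csv"))
        writeTruthJSON(core$truth, file.path(dir, "truth.json"))
    }
    out
}

## minimal deterministic GFF3 writer: one gene + one CDS per locus
.writeGFF3 <- function(annotations, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (i in seq_len(nrow(annotations))) {
        a <- annotations[i, ]
        s1 <- a$start + 1L  # GFF3 is 1-based inclusive
        writeLines(sprintf("%s\tssrOrigin\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                           a$seq_id, s1, a$end, a$locus_id), con)
        if (a$is_coding)
            writeLines(sprintf(
                "%s\tssrOrigin\tCDS\t%d\t%d\t.\t+\t0\tID=cds-%s;Parent=%s",
                a$seq_id, s1, a$end, a$locus_id, a$locus_id), con)
    }
    invisible(path)
}

#' @rdname ssr-io
#' @export
writeTruthJSON <- function(x, path) {
    jsonlite::write_json(list(planted_conserved = x$planted_conserved,
                              noise_features = x$noise_features),
                         path, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname ssr-io
#' @export
readTruthJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    truth <- list(planted_conserved = lapply(obj$planted_conserved,
                                             as.character),
                  noise_features = as.character(obj$noise_features))
    class(truth) <- "ssr_truth"
    truth
}

#' Inject N characters into planted arrays of simulated genomes
#'
#' Testing helper that corrupts chosen planted arrays by overwriting one
#' base inside each with \code{N}, emulating low-coverage consensus calls.
#'
#' @param genomes result of \code{\link{simulateGenomes}}.
#' @param feature_keys keys of planted features to corrupt.
#' @param samples sample ids to corrupt (default: all carrying the feature).
#' @return the modified genomes list.
#' @export
injectN <- function(genomes, feature_keys, samples = NULL) {
    ann <- genomes$annotations
    for (key in feature_keys) {
        p <- parseFeatureKey(key)
        a <- ann[ann$locus_id == p$locus_id, ]
        if (nrow(a) != 1L) stop("unknown locus for key ", key)
        mid <- (a$start + a$end) %/% 2L + 1L
        targets <- if (is.null(samples)) names(genomes$samples) else samples
        for (s in targets)
            substr(genomes$samples[[s]], mid, mid) <- "N"
    }
    genomes
}
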