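#' Default pipeline configuration
#'
#' Hierarchical settings for the simulate, extract, select, bench and
#' cluster stages. \code{selection$cap = NULL} means the natural size of
#' the group-wise conserved selection defines the cap for the other three
#' strategies.
#'
#' @return nested named list of defaults.
#' @export
defaultPipelineConfig <- function() {
    list(seed = 1L,
         output_dir = "ssr_pipeline_out",
         stages = list(simulate = TRUE, extract = TRUE, select = TRUE,
                       bench = TRUE, cluster = TRUE),
         paths = list(fasta_dir = NULL, gff3 = NULL, labels_csv = NULL,
                      reference_fasta = NULL, feature_matrix_csv = NULL),
         simulate = list(genome_mode = TRUE,
                         samples_per_group = c(PG = 8L, CO = 4L, MP = 12L,
                                               FG = 14L),
                         n_conserved_per_group = c(PG = 0L, CO = 8L,
                                                   MP = 6L, FG = 5L),
                         n_loci = 240L, n_noise_features = 200L,
                         noise_presence_prob = 0.15,
                         heterogeneous_groups = "PG",
                         locus_length = 400L),
         extraction = list(thresholds = c(10L, 5L, 4L, 3L, 3L, 3L),
                           interrupt_max_bp = 4L, compound_gap_bp = 10L,
                           coding_only = FALSE, drop_n = TRUE),
         selection = list(cap = NULL, k1 = 5000L,
                          hybrid_iterations = 150L, hybrid_folds = 4L,
                          lasso_c_range = c(1e-3, 1e3),
                          lasso_iterations = 25L),
         bench = list(tune_iterations = 100L, tune_folds = 3L,
                      tune_method = "smbo", replicates = 30L, k_max = 30L),
         cluster = list())
}

.mergeConfig <- function(defaults, user, path = character()) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(paste(c(path, ""), collapse = "."),
                   unknown, sep = "", collapse = ", "), call. = FALSE)
    for (k in names(user)) {
        if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
            !is.null(names(defaults[[k]])))
            defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]],
                                          c(path, k))
        else defaults[k] <- user[k]
    }
    defaults
}

#' Validate a pipeline configuration file
#'
#' Parses a YAML file, fills in documented defaults, rejects unknown keys,
#' and checks stage invariants (input paths must exist for stages that
#' need them when simulation is disabled).
#'
#' @param path YAML configuration file, or a named list already in memory.
#' @return validated config list of class \code{"ssr_pipeline_config"}.
#' @export
validateConfig <- function(path) {
    user <- if (is.character(path)) yaml::read_yaml(path) else path
    if (is.null(user)) user <- list()
    cfg <- .mergeConfig(defaultPipelineConfig(), user)
    if (is.null(cfg$seed)) stop("configuration error: seed must be set")
    cfg$seed <- as.integer(cfg$seed)
    if (!cfg$stages$simulate && cfg$stages$extract) {
        for (p in c("fasta_dir", "gff3", "labels_csv")) {
            if (is.null(cfg$paths[[p]]) || !file.exists(cfg$paths[[p]]))
                stop("configuration error: paths$", p,
                     " must exist when extract runs without simulate")
        }
    }
    class(cfg) <- "ssr_pipeline_config"
    cfg
}

.stageSeed <- function(cfg, stage) {
    offs <- c(simulate = 101L, extract = 211L, select = 307L,
              bench = 401L, cluster = 503L)
    cfg$seed + offs[[stage]]
}

.logStage <- function(logcon, stage, event, ...) {
    msg <- sprintf(...)
    message(sprintf("[%s] %s: %s", stage, event, msg))
    writeLines(jsonlite::toJSON(list(stage = stage, event = event,
                                     detail = msg), auto_unbox = TRUE),
               logcon)
}

#' Run the full origin-inference pipeline
#'
#' Executes the enabled stages in order -- simulate, extract, select,
#' bench, cluster -- writing each stage's interface files plus a manifest
#' and a provenance record under \code{config$output_dir}. Clustering runs
#' on the best (selection, classifier) combination's best feature panel
#' (highest mean weighted F1, ties towards fewer markers).
#'
#' @param config a validated configuration (see
#'   \code{\link{validateConfig}}); a plain list is validated on entry.
#' @return invisible list with the in-memory results of each stage.
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "ssr_pipeline_config"))
        config <- validateConfig(config)
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    manifest <- character(0)
    declare <- function(p) { manifest <<- c(manifest, p); p }
    logcon <- file(file.path(out, "pipeline_log.jsonl"), "w")
    on.exit(close(logcon))
    bundle <- list()
    stage <- "init"
    tryCatch({
        ## ---- simulate ----
        genomes <- NULL
        fs <- NULL
        labels <- NULL
        if (config$stages$simulate) {
            stage <- "simulate"
            simargs <- config$simulate
            for (f in c("samples_per_group", "n_conserved_per_group"))
                simargs[[f]] <- unlist(simargs[[f]])
            simargs$heterogeneous_groups <-
                as.character(unlist(simargs$heterogeneous_groups))
            simargs$genome_mode <- isTRUE(simargs$genome_mode)
            simargs$seed <- .stageSeed(config, "simulate")
            simcfg <- do.call(simulationConfig, simargs)
            simdir <- file.path(out, "simulate")
            if (simcfg$genome_mode) {
                genomes <- simulateGenomes(simcfg, dir = simdir)
                declare(file.path(simdir, "reference.fasta"))
                declare(file.path(simdir, "loci.gff3"))
                declare(file.path(simdir, "labels.csv"))
                declare(file.path(simdir, "truth.json"))
                for (s in names(genomes$samples))
                    declare(file.path(simdir, "samples",
                                      paste0(s, ".fasta")))
                labels <- genomes$labels
                .logStage(logcon, stage, "done",
                          "%d samples, %d loci", length(genomes$samples),
                          nrow(genomes$annotations))
            } else {
                sim <- simulateFeatureTable(simcfg)
                dir.create(simdir, recursive = TRUE, showWarnings = FALSE)
                fs <- sim$features
                labels <- sim$labels
                writeFeatureMatrixCSV(fs, declare(file.path(simdir,
                                                  "features.csv")))
                writeTruthJSON(sim$truth, declare(file.path(simdir,
                                                  "truth.json")))
                .logStage(logcon, stage, "done", "%d features x %d samples",
                          nrow(fs), ncol(fs))
            }
            bundle$simulate <- if (is.null(genomes)) fs else genomes
        }
        ## ---- extract ----
        if (config$stages$extract && (is.null(fs))) {
            stage <- "extract"
            ex <- config$extraction
            if (!is.null(genomes)) {
                seqsBySample <- lapply(genomes$samples, function(s)
                    c(chr1 = s))
                annotations <- genomes$annotations
                labels <- genomes$labels
            } else {
                files <- list.files(config$paths$fasta_dir,
                                    pattern = "\\.fa(sta)?$",
                                    full.names = TRUE)
                seqsBySample <- lapply(files, function(f) {
                    x <- Biostrings::readDNAStringSet(f)
                    stats::setNames(as.character(x),
                                    sub("\\s.*", "", names(x)))
                })
                names(seqsBySample) <- sub("\\.fa(sta)?$", "",
                                           basename(files))
                annotations <- readLocusAnnotations(config$paths$gff3)
                labels <- readLabelsCSV(config$paths$labels_csv)
            }
            callsBySample <- lapply(names(seqsBySample), function(s) {
                calls <- detectSSRs(seqsBySample[[s]],
                                    thresholds = ex$thresholds,
                                    sample_id = s)
                classifyCalls(calls, ex$interrupt_max_bp,
                              ex$compound_gap_bp,
                              sequences = stats::setNames(
                                  list(seqsBySample[[s]]), s))
            })
            names(callsBySample) <- names(seqsBySample)
            fs <- buildFeatureMatrix(callsBySample, annotations, labels,
                                     coding_only = ex$coding_only,
                                     drop_n = ex$drop_n,
                                     exclude_reference_sample = "reference")
            exdir <- file.path(out, "extract")
            dir.create(exdir, recursive = TRUE, showWarnings = FALSE)
            writeCallsTSV(do.call(rbind, callsBySample),
                          declare(file.path(exdir, "calls.tsv")))
            writeFeatureMatrixCSV(fs, declare(file.path(exdir,
                                              "features.csv")))
            .logStage(logcon, stage, "done", "%d features x %d samples",
                      nrow(fs), ncol(fs))
            bundle$features <- fs
        }
        if (is.null(fs) && !is.null(config$paths$feature_matrix_csv))
            fs <- readFeatureMatrixCSV(config$paths$feature_matrix_csv)
        ## ---- select ----
        selections <- NULL
        if (config$stages$select) {
            stage <- "select"
            if (is.null(fs)) stop("no feature matrix available")
            seed <- .stageSeed(config, "select")
            scfg <- config$selection
            gc <- gcSSRSelect(fs)
            cap <- if (is.null(scfg$cap))
                max(1L, length(gc@features)) else as.integer(scfg$cap)
            selections <- list(
                gc,
                selectKBest(fs, k = cap),
                hybridSelect(fs, k1 = min(scfg$k1, nrow(fs)),
                             k2 = min(cap, nrow(fs)),
                             search_iterations = scfg$hybrid_iterations,
                             folds = scfg$hybrid_folds, seed = seed),
                lassoSelect(fs, cap = cap,
                            c_range = scfg$lasso_c_range,
                            search_iterations = scfg$lasso_iterations,
                            seed = seed))
            seldir <- file.path(out, "select")
            dir.create(seldir, recursive = TRUE, showWarnings = FALSE)
            for (sel in selections) {
                writeSelectionJSON(sel, declare(file.path(seldir,
                    paste0(sel@method, ".json"))))
                writeSelectionCSV(sel, declare(file.path(seldir,
                    paste0(sel@method, ".csv"))))
            }
            .logStage(logcon, stage, "done",
                      "subset sizes: %s",
                      paste(vapply(selections, function(s)
                          length(s@features), 1L), collapse = "/"))
            bundle$selections <- selections
        }
        ## ---- bench ----
        bench <- NULL
        if (config$stages$bench) {
            stage <- "bench"
            if (is.null(selections)) stop("no selections available")
            seed <- .stageSeed(config, "bench")
            bcfg <- config$bench
            classifiers <- list(
                classifierSpec("linear_svc", seed = seed),
                classifierSpec("random_forest", seed = seed),
                classifierSpec("gradient_boosting", seed = seed))
            nonEmpty <- Filter(function(s) length(s@features) > 0,
                               selections)
            bench <- runBenchmark(fs, nonEmpty, classifiers,
                config = benchConfig(tune_iterations = bcfg$tune_iterations,
                                     tune_folds = bcfg$tune_folds,
                                     tune_method = bcfg$tune_method,
                                     replicates = bcfg$replicates,
                                     k_max = bcfg$k_max,
                                     base_seed = seed))
            bdir <- file.path(out, "bench")
            dir.create(bdir, recursive = TRUE, showWarnings = FALSE)
            utils::write.csv(bench$summary,
                             declare(file.path(bdir, "summary.csv")),
                             row.names = FALSE)
            for (id in names(bench$results)) {
                r <- bench$results[[id]]
                jsonlite::write_json(
                    list(selection = r@selectionMethod,
                         classifier = r@classifierKind, best_k = r@bestK,
                         best_features = r@bestFeatures,
                         means = as.data.frame(r@curve@means),
                         sds = as.data.frame(r@curve@sds),
                         mean_confusion = r@meanConfusion,
                         importances = as.list(r@importances)),
                    declare(file.path(bdir, paste0(gsub(" x ", "_", id),
                                                   ".json"))),
                    auto_unbox = TRUE, digits = NA, pretty = TRUE)
            }
            .logStage(logcon, stage, "done", "%d combinations, %d failures",
                      length(bench$results), length(bench$failures))
            bundle$bench <- bench
        }
        ## ---- cluster ----
        if (config$stages$cluster) {
            stage <- "cluster"
            if (is.null(bench) || !length(bench$results))
                stop("no benchmark results available")
            summ <- bench$summary
            ord <- order(-summ$mean_f1, summ$ssrs_incorporated,
                         summ$method, summ$classifier)
            bestId <- paste(summ$method[ord[1]], summ$classifier[ord[1]],
                            sep = " x ")
            best <- bench$results[[bestId]]
            d <- jaccardDistance(fs, features = best@bestFeatures)
            pc <- pcoaAnalysis(d)
            tree <- upgmaTree(d)
            cdir <- file.path(out, "cluster")
            dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
            writeDistanceCSV(d, declare(file.path(cdir,
                                                  "jaccard_distance.csv")))
            writePCoACSV(pc, declare(file.path(cdir, "pcoa.csv")))
            declare(file.path(cdir, "pcoa_eigen.json"))
            writeNewick(tree, declare(file.path(cdir, "upgma.nwk")))
            jsonlite::write_json(list(best_combination = bestId,
                                      features = best@bestFeatures),
                                 declare(file.path(cdir,
                                                   "best_combination.json")),
                                 auto_unbox = TRUE, pretty = TRUE)
            .logStage(logcon, stage, "done", "clustered on %s (%d markers)",
                      bestId, best@bestK)
            bundle$cluster <- list(best = bestId, distance = d, pcoa = pc,
                                   tree = tree)
        }
    }, error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), call. = FALSE)
    })
    ## provenance + manifest
    prov <- list(seed = config$seed,
                 stages = config$stages,
                 timestamp = format(Sys.time(), tz = "UTC"),
                 package_version =
                     as.character(utils::packageVersion("ssrOrigin")))
    jsonlite::write_json(prov, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(list(files = manifest),
                         file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(bundle)
}
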