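#' Default minimum repeat counts per motif length
#'
#' The smallest number of full unit copies a perfect run must reach to be
#' reported, indexed mono- to hexa-nucleotide. Defaults are the smallest
#' counts observed among published marker panels for this marker type:
#' mono 10, di 5, tri 4, tetra 3, penta 3, hexa 3.
#'
#' @return named integer vector of length 6.
#' @export
defaultThresholds <- function() {
    c(mono = 10L, di = 5L, tri = 4L, tetra = 3L, penta = 3L, hexa = 3L)
}

.emptyCalls <- function() {
    data.frame(sample_id = character(), seq_id = character(),
               start = integer(), end = integer(), motif = character(),
               repeat_count = integer(), ssr_class = character(),
               contains_n = logical(), stringsAsFactors = FALSE)
}

## Scan one sequence (character scalar) for maximal perfect repeat runs.
## For each unit length u, positions where s[i] == s[i+u] are computed in one
## vectorised pass; a maximal TRUE run of length L marks a periodic region of
## length L + u whose full-copy count is floor((L+u)/u). Runs are anchored at
## the region start, reported with the motif as it first appears there, and
## suppressed when that motif is itself a repetition of a shorter unit (the
## run is then already reported under the shorter period).
.scanSequence <- function(seq, thresholds) {
    n <- nchar(seq)
    if (n == 0L) return(.emptyCalls())
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    bad <- !chars %in% c("A", "C", "G", "T", "N")
    if (any(bad))
        stop("invalid character(s) in sequence: ",
             paste(unique(chars[bad]), collapse = ", "))
    ok <- chars != "N"
    out <- vector("list", 6L)
    for (u in 1:6) {
        if (n <= u) break
        idx <- seq_len(n - u)
        eq <- chars[idx] == chars[idx + u] & ok[idx] & ok[idx + u]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        hit <- which(r$values)
        if (!length(hit)) next
        a <- starts[hit]
        copies <- ((ends[hit] - a + 1L) + u) %/% u
        keep <- copies >= thresholds[u]
        if (!any(keep)) next
        a <- a[keep]; copies <- copies[keep]
        motif <- substring(seq, a, a + u - 1L)
        prim <- isPrimitiveMotif(motif)
        if (!any(prim)) next
        a <- a[prim]; copies <- copies[prim]; motif <- motif[prim]
        out[[u]] <- data.frame(start = a - 1L, end = a - 1L + u * copies,
                               motif = motif, repeat_count = copies,
                               stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(out) || nrow(out) == 0L) return(.emptyCalls())
    out <- out[order(out$start, out$end), , drop = FALSE]
    data.frame(sample_id = NA_character_, seq_id = NA_character_,
               start = out$start, end = out$end, motif = out$motif,
               repeat_count = out$repeat_count, ssr_class = "perfect",
               contains_n = FALSE, stringsAsFactors = FALSE)
}

#' Detect perfect SSR runs in nucleotide sequences
#'
#' Finds every maximal perfect tandem repeat of a primitive 1-6 bp motif
#' whose number of full unit copies meets the per-unit-length threshold.
#' Runs are reported with the primitive motif as it first appears at the
#' region start; the same run is never reported again under a non-primitive
#' unit (e.g. \code{ATATATAT} is one \code{(AT)4} call, never
#' \code{(ATAT)2}). Partial trailing units do not count towards
#' \code{repeat_count} and are excluded from the reported span, so
#' \code{end - start == nchar(motif) * repeat_count} for every call.
#' Stretches containing \code{N} never extend a run.
#'
#' @param sequences a named character vector, a named list of character
#'   scalars, or a \code{\link[Biostrings]{DNAStringSet}}; names are used as
#'   \code{seq_id}.
#' @param thresholds integer vector of length 6, minimum full-copy counts for
#'   unit lengths 1-6 (see \code{\link{defaultThresholds}}).
#' @param sample_id optional sample identifier stamped on every call.
#' @return A data.frame of SSR calls with columns \code{sample_id},
#'   \code{seq_id}, \code{start}, \code{end} (0-based half-open),
#'   \code{motif}, \code{repeat_count}, \code{ssr_class} (all
#'   \code{"perfect"} here; see \code{\link{classifyCalls}}) and
#'   \code{contains_n}.
#' @examples
#' detectSSRs(c(chr1 = "TCATCATCATCATCA"))
#' @export
detectSSRs <- function(sequences, thresholds = defaultThresholds(),
                       sample_id = NA_character_) {
    if (methods::is(sequences, "DNAStringSet"))
        sequences <- as.character(sequences)
    if (is.list(sequences)) sequences <- unlist(sequences)
    if (!is.character(sequences))
        stop("'sequences' must be character or DNAStringSet")
    if (any(thresholds < 1L) || length(thresholds) != 6L)
        stop("'thresholds' must be 6 positive minimum counts")
    if (is.null(names(sequences)))
        names(sequences) <- if (length(sequences) == 1L) "seq1" else
            paste0("seq", seq_along(sequences))
    res <- lapply(names(sequences), function(id) {
        calls <- .scanSequence(sequences[[id]], as.integer(thresholds))
        if (nrow(calls)) {
            calls$seq_id <- id
            calls$sample_id <- sample_id
        }
        calls
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Classify SSR calls as perfect, imperfect or compound
#'
#' Applies two merge/annotation rules to position-sorted calls within each
#' (sample, sequence): consecutive same-motif perfect runs whose gap is at
#' most \code{interrupt_max_bp} merge into one imperfect call whose count is
#' the sum of unit copies; after merging, two adjacent calls with different
#' motifs separated by at most \code{compound_gap_bp} are both marked
#' compound (compound status overrides imperfect for such calls). All other
#' calls keep their class. When \code{sequences} is supplied, merged spans
#' are rechecked for \code{N} characters and flagged via \code{contains_n};
#' otherwise the flag is the union of the merged parts.
#'
#' @param calls a calls data.frame from \code{\link{detectSSRs}}.
#' @param interrupt_max_bp maximum interruption length for a same-motif
#'   merge (default 4).
#' @param compound_gap_bp maximum gap for compound annotation (default 10).
#' @param sequences optional named list: \code{sequences[[sample_id]]} is a
#'   named character vector of that sample's sequences by \code{seq_id}.
#' @return The calls data.frame with updated \code{ssr_class},
#'   \code{repeat_count}, spans and \code{contains_n}.
#' @export
classifyCalls <- function(calls, interrupt_max_bp = 4L,
                          compound_gap_bp = 10L, sequences = NULL) {
    if (nrow(calls) == 0L) return(calls)
    pieces <- split(calls, list(calls$sample_id, calls$seq_id), drop = TRUE)
    pieces <- lapply(pieces, function(df) {
        df <- df[order(df$start, df$end), , drop = FALSE]
        ## pass 1: same-motif merges
        merged <- df[1, , drop = FALSE]
        for (i in seq_len(nrow(df))[-1]) {
            cur <- merged[nrow(merged), ]
            nxt <- df[i, ]
            gap <- nxt$start - cur$end
            if (nxt$motif == cur$motif && gap >= 0 &&
                gap <= interrupt_max_bp) {
                cur$end <- nxt$end
                cur$repeat_count <- cur$repeat_count + nxt$repeat_count
                cur$ssr_class <- "imperfect"
                cur$contains_n <- cur$contains_n || nxt$contains_n
                if (!is.null(sequences)) {
                    s <- sequences[[cur$sample_id]]
                    if (!is.null(s) && cur$seq_id %in% names(s)) {
                        span <- substr(s[[cur$seq_id]], cur$start + 1L,
                                       cur$end)
                        cur$contains_n <- grepl("N", span, fixed = TRUE)
                    }
                }
                merged[nrow(merged), ] <- cur
            } else {
                merged <- rbind(merged, nxt)
            }
        }
        ## pass 2: compound marking across different motifs
        if (nrow(merged) > 1L) {
            for (i in seq_len(nrow(merged) - 1L)) {
                gap <- merged$start[i + 1L] - merged$end[i]
                if (merged$motif[i + 1L] != merged$motif[i] &&
                    gap <= compound_gap_bp) {
                    merged$ssr_class[c(i, i + 1L)] <- "compound"
                }
            }
        }
        merged
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out[order(out$sample_id, out$seq_id, out$start), , drop = FALSE]
}

#' Read locus annotations from a GFF3 file
#'
#' Imports gene features and flags each as coding when at least one CDS
#' feature overlaps it. GFF3 coordinates (1-based inclusive) are converted
#' to the 0-based half-open convention used throughout the package.
#'
#' @param path GFF3 file.
#' @return data.frame with columns \code{locus_id}, \code{seq_id},
#'   \code{start}, \code{end} (0-based half-open), \code{is_coding}.
#' @export
readLocusAnnotations <- function(path) {
    g <- rtracklayer::import(path, format = "gff3")
    genes <- g[g$type == "gene"]
    if (!length(genes)) stop("no gene features in ", path)
    ids <- genes$ID
    if (is.null(ids) || anyNA(ids)) {
        alt <- genes$Name
        ids <- ifelse(is.na(ids) | is.null(ids), alt, ids)
    }
    cds <- g[g$type == "CDS"]
    coding <- rep(FALSE, length(genes))
    if (length(cds))
        coding <- IRanges::overlapsAny(genes, cds)
    data.frame(locus_id = as.character(ids),
               seq_id = as.character(GenomicRanges::seqnames(genes)),
               start = GenomicRanges::start(genes) - 1L,
               end = GenomicRanges::end(genes),
               is_coding = coding, stringsAsFactors = FALSE)
}

#' Assign SSR calls to annotated loci
#'
#' Each call receives the \code{locus_id} of the annotation with maximal
#' base-pair overlap; ties are broken by the smaller annotation start. Calls
#' overlapping no annotation get a synthetic intergenic id,
#' \code{intergenic:<seq_id>:<floor(start/10000)>}.
#'
#' @param calls calls data.frame (see \code{\link{detectSSRs}}).
#' @param annotations annotation data.frame (see
#'   \code{\link{readLocusAnnotations}}).
#' @return \code{calls} with an added \code{locus_id} column.
#' @export
assignLoci <- function(calls, annotations) {
    if (nrow(calls) == 0L) {
        calls$locus_id <- character(0)
        return(calls)
    }
    callGR <- GenomicRanges::GRanges(calls$seq_id,
        IRanges::IRanges(calls$start + 1L, calls$end))
    annGR <- GenomicRanges::GRanges(annotations$seq_id,
        IRanges::IRanges(annotations$start + 1L, annotations$end))
    hits <- GenomicRanges::findOverlaps(callGR, annGR)
    locus <- sprintf("intergenic:%s:%d", calls$seq_id,
                     calls$start %/% 10000L)
    if (length(hits)) {
        qh <- S4Vectors::queryHits(hits)
        sh <- S4Vectors::subjectHits(hits)
        ov <- GenomicRanges::width(IRanges::pintersect(callGR[qh], annGR[sh]))
        ## per call: max overlap, tie -> smaller annotation start
        o <- order(qh, -ov, annotations$start[sh])
        first <- !duplicated(qh[o])
        locus[qh[o][first]] <- annotations$locus_id[sh[o][first]]
    }
    calls$locus_id <- locus
    calls
}

#' Build the binary cross-sample SSR presence/absence matrix
#'
#' Collects the union of feature keys (locus, motif, repeat count) observed
#' in at least one retained sample and sets entry (feature, sample) to 1
#' when that sample has a matching call. The reference sample, if named,
#' contributes no row and no column; calls flagged \code{contains_n} are
#' dropped when \code{drop_n} is TRUE; with \code{coding_only} only keys at
#' coding loci are kept.
#'
#' @param calls_by_sample named list of call data.frames, one per sample
#'   (locus ids are assigned via \code{\link{assignLoci}} when missing).
#' @param annotations locus annotation data.frame.
#' @param labels named character vector: sample id -> origin group.
#' @param coding_only keep only features at coding loci (default FALSE).
#' @param drop_n drop calls containing N (default TRUE).
#' @param exclude_reference_sample optional sample id to exclude.
#' @return An \code{\linkS4class{SSRFeatureSet}}.
#' @export
buildFeatureMatrix <- function(calls_by_sample, annotations, labels,
                               coding_only = FALSE, drop_n = TRUE,
                               exclude_reference_sample = NULL) {
    samples <- names(calls_by_sample)
    if (!is.null(exclude_reference_sample))
        samples <- setdiff(samples, exclude_reference_sample)
    missing <- setdiff(samples, names(labels))
    if (length(missing))
        stop("unlabelled sample(s): ", paste(missing, collapse = ", "))
    coding_map <- stats::setNames(annotations$is_coding,
                                  annotations$locus_id)
    keysBySample <- lapply(samples, function(s) {
        df <- calls_by_sample[[s]]
        if (nrow(df) == 0L) return(character(0))
        if (!"locus_id" %in% colnames(df))
            df <- assignLoci(df, annotations)
        if (drop_n) df <- df[!df$contains_n, , drop = FALSE]
        if (coding_only) {
            isc <- coding_map[df$locus_id]
            isc[is.na(isc)] <- FALSE  # intergenic ids are non-coding
            df <- df[isc, , drop = FALSE]
        }
        unique(makeFeatureKey(df$locus_id, df$motif, df$repeat_count))
    })
    names(keysBySample) <- samples
    allKeys <- sort(unique(unlist(keysBySample)))
    m <- matrix(0L, nrow = length(allKeys), ncol = length(samples),
                dimnames = list(allKeys, samples))
    for (s in samples) m[keysBySample[[s]], s] <- 1L
    SSRFeatureSet(m, labels)
}
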