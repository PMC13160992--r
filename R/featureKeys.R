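#' Build and parse SSR feature keys
#'
#' A feature is identified across samples by the triple (locus, motif,
#' repeat count). The canonical machine key is \code{"locus|motif|count"};
#' the display form used in marker tables is \code{"locus (MOTIF)count"},
#' e.g. \code{"LOC115707832 (AAG)5"}. Both serialisations are bijective.
#'
#' @param locus_id,motif,repeat_count vectors of equal length.
#' @param key character vector of canonical keys.
#' @return \code{makeFeatureKey}: character keys. \code{parseFeatureKey}: a
#'   data.frame with columns \code{locus_id}, \code{motif},
#'   \code{repeat_count}. \code{formatFeatureKey}: display strings.
#' @examples
#' k <- makeFeatureKey("LOC115707832", "AAG", 5L)
#' parseFeatureKey(k)
#' formatFeatureKey(k)
#' @export
makeFeatureKey <- function(locus_id, motif, repeat_count) {
    stopifnot(!grepl("|", locus_id, fixed = TRUE),
              !grepl("|", motif, fixed = TRUE))
    paste(locus_id, motif, as.integer(repeat_count), sep = "|")
}

#' @rdname makeFeatureKey
#' @export
parseFeatureKey <- function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad))
        stop("malformed feature key(s): ",
             paste(utils::head(key[bad], 3), collapse = ", "))
    m <- do.call(rbind, parts)
    data.frame(locus_id = m[, 1], motif = m[, 2],
               repeat_count = as.integer(m[, 3]),
               stringsAsFactors = FALSE)
}

#' @rdname makeFeatureKey
#' @export
formatFeatureKey <- function(key) {
    p <- parseFeatureKey(key)
    sprintf("%s (%s)%d", p$locus_id, p$motif, p$repeat_count)
}

## primitive motif check: a motif is primitive when it is not a whole-number
## repetition of any shorter unit
isPrimitiveMotif <- function(motif) {
    vapply(motif, function(m) {
        u <- nchar(m)
        if (u <= 1L) return(TRUE)
        for (d in seq_len(u - 1L)) {
            if (u %% d != 0L) next
            unit <- substr(m, 1L, d)
            if (m == paste(rep(unit, u %/% d), collapse = "")) return(FALSE)
        }
        TRUE
    }, logical(1), USE.NAMES = FALSE)
}
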