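# classify one modified k-mer: returns the 1-based mod position if the k-mer
# has exactly one mod code sitting in a complete, correctly spelled motif,
# otherwise NA with a reason attribute
singleModPosition <- function(kmer, scheme, k) {
    chars <- strsplit(kmer, "")[[1L]]
    at <- which(chars == scheme@modCode)
    if (length(at) != 1L)
        return(structure(NA_integer_,
                         reason = if (length(at)) "multi-modification"
                                  else "no modification code"))
    m <- at
    fp <- motifFootprint(scheme, m)[[1L]]
    if (any(fp < 1L) || any(fp > k))
        return(structure(NA_integer_, reason = "incomplete motif"))
    want <- strsplit(scheme@motif, "")[[1L]]
    want[scheme@modOffset + 1L] <- scheme@modCode
    if (!all(chars[fp] == want))
        return(structure(NA_integer_, reason = "motif context mismatch"))
    m
}

#' Compute the delta-C table for trained modified k-mers
#'
#' For every trained k-mer, delta-C is the modified model's expected current
#' level minus the level of the canonical counterpart (modification code
#' replaced by its canonical base) in the canonical model, e.g. AMA minus
#' ACA for CpG methylation at k = 3. Only single-modification,
#' complete-motif k-mers enter the table; multi-modification or
#' incomplete-motif members of \code{trained} are skipped with a warning.
#'
#' @param canonical Canonical \linkS4class{KmerModel}.
#' @param modified Modified \linkS4class{KmerModel} holding trained levels.
#' @param scheme A \linkS4class{ModificationScheme}.
#' @param trained Character vector of trained modified k-mers; defaults to
#'   all modified k-mers present in \code{modified}.
#' @return A \linkS4class{DeltaTable}.
#' @export
computeDelta <- function(canonical, modified, scheme,
                         trained = modifiedKmers(modified)) {
    k <- modified@k
    pos <- vapply(trained, function(x) {
        p <- singleModPosition(x, scheme, k)
        as.integer(p)
    }, integer(1L))
    if (anyNA(pos)) {
        bad <- trained[is.na(pos)]
        warning("skipping ", length(bad),
                " trained k-mer(s) that are not single-modification ",
                "complete-motif (e.g. ", head(bad, 1L), ")")
        trained <- trained[!is.na(pos)]
        pos <- pos[!is.na(pos)]
    }
    hit_mod <- match(trained, modified@entries$kmer)
    if (anyNA(hit_mod))
        stop("trained k-mer(s) absent from modified model: ",
             paste(head(trained[is.na(hit_mod)], 5L), collapse = ", "))
    counterparts <- canonicalizeKmers(trained, scheme)
    hit_can <- match(counterparts, canonical@entries$kmer)
    if (anyNA(hit_can))
        stop("canonical counterpart(s) absent from canonical model: ",
             paste(head(counterparts[is.na(hit_can)], 5L), collapse = ", "))
    rec <- data.frame(kmer = trained,
                      mod_position = pos,
                      delta = modified@entries$level_mean[hit_mod] -
                              canonical@entries$level_mean[hit_can],
                      stringsAsFactors = FALSE)
    rownames(rec) <- NULL
    new("DeltaTable", scheme = scheme, k = as.integer(k), records = rec)
}

#' Construct a DeltaTable directly from records
#'
#' @param records \code{data.frame} with columns \code{kmer},
#'   \code{mod_position}, \code{delta}.
#' @param scheme A \linkS4class{ModificationScheme}.
#' @param k k-mer length.
#' @return A \linkS4class{DeltaTable}.
#' @export
DeltaTable <- function(records, scheme, k) {
    records <- as.data.frame(records)
    records$kmer <- as.character(records$kmer)
    records$mod_position <- as.integer(records$mod_position)
    new("DeltaTable", scheme = scheme, k = as.integer(k), records = records)
}

#' @describeIn DeltaTable The records \code{data.frame}.
#' @param delta A \linkS4class{DeltaTable}.
#' @export
deltaRecords <- function(delta) delta@records

setMethod("show", "DeltaTable", function(object) {
    cat("DeltaTable: ", nrow(object@records), " trained k-mers (k = ",
        object@k, ", motif ", object@scheme@motif, ")\n", sep = "")
    if (nrow(object@records)) {
        s <- summarizeByPosition(object)
        cat("  per-position medians: ",
            paste(sprintf("%d: %.3f (n=%d)", s$mod_position, s$median,
                          s$count), collapse = ", "), "\n", sep = "")
    }
})

#' Per-position median delta-C
#'
#' Groups the delta-C records by modification position and reports the
#' median shift and group size. These medians are exactly the position-rule
#' shifts \code{\link{deriveRules}} assigns in its first step.
#'
#' @param delta A \linkS4class{DeltaTable}.
#' @return \code{data.frame} with columns \code{mod_position},
#'   \code{median}, \code{count}, ordered by position.
#' @export
summarizeByPosition <- function(delta) {
    r <- delta@records
    if (!nrow(r)) stop("empty delta table")
    ms <- sort(unique(r$mod_position))
    data.frame(mod_position = ms,
               median = vapply(ms, function(m)
                   median(r$delta[r$mod_position == m]), numeric(1L)),
               count = vapply(ms, function(m)
                   sum(r$mod_position == m), integer(1L)))
}
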