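#' Compare expected levels of two k-mer models
#'
#' Pairs the two models' \code{level_mean} values on the intersection of a
#' k-mer subset and reports n, Pearson correlation, RMSE and the largest
#' absolute difference. Subsets: \code{"all"} (every shared k-mer),
#' \code{"trained"} (shared modified k-mers in \code{trained}),
#' \code{"imputed"} (shared modified k-mers not in \code{trained}).
#' With \code{deltaSpace = TRUE} the comparison is made on delta-C values
#' (level minus canonical counterpart's level) instead of raw levels,
#' which requires a \code{scheme} and a \code{canonical} model.
#'
#' @param a,b \linkS4class{KmerModel}s.
#' @param subset \code{"all"}, \code{"trained"} or \code{"imputed"}.
#' @param trained Character vector of trained k-mers (required for the
#'   trained/imputed subsets).
#' @param deltaSpace Compare delta-C values instead of levels.
#' @param scheme,canonical Needed when \code{deltaSpace = TRUE}.
#' @return A \linkS4class{ComparisonReport}.
#' @export
compareModels <- function(a, b, subset = c("all", "trained", "imputed"),
                          trained = NULL, deltaSpace = FALSE,
                          scheme = NULL, canonical = NULL) {
    subset <- match.arg(subset)
    shared <- intersect(a@entries$kmer, b@entries$kmer)
    if (subset != "all") {
        if (is.null(trained))
            stop("subset '", subset, "' requires a trained k-mer set")
        mod <- shared[grepl("[^ACGT]", shared)]
        shared <- if (subset == "trained") intersect(mod, trained)
                  else setdiff(mod, trained)
    }
    if (!length(shared))
        stop("empty k-mer intersection for subset '", subset, "'")
    va <- unname(levelMeans(a, shared))
    vb <- unname(levelMeans(b, shared))
    if (deltaSpace) {
        if (is.null(scheme) || is.null(canonical))
            stop("deltaSpace = TRUE requires scheme and canonical")
        base <- unname(levelMeans(canonical,
                                  canonicalizeKmers(shared, scheme)))
        va <- va - base
        vb <- vb - base
    }
    d <- va - vb
    new("ComparisonReport", n = length(shared),
        pearson = if (length(shared) >= 2L && stats::sd(va) > 0 &&
                      stats::sd(vb) > 0) cor(va, vb) else NA_real_,
        rmse = sqrt(mean(d^2)), maxAbsDiff = max(abs(d)), subset = subset)
}

#' @describeIn ComparisonReport Coerce to a one-row \code{data.frame}.
#' @param report A \linkS4class{ComparisonReport}.
#' @export
reportAsDataFrame <- function(report)
    data.frame(subset = report@subset, n = report@n,
               pearson = report@pearson, rmse = report@rmse,
               max_abs_diff = report@maxAbsDiff)

#' @describeIn ComparisonReport RMSE of the comparison.
#' @export
rmse <- function(report) report@rmse

#' @describeIn ComparisonReport Pearson correlation.
#' @export
pearson <- function(report) report@pearson

setMethod("show", "ComparisonReport", function(object) {
    cat(sprintf(paste0("ComparisonReport [%s]: n = %d, pearson = %.4f, ",
                       "rmse = %.4f, max |diff| = %.4f\n"),
                object@subset, object@n, object@pearson, object@rmse,
                object@maxAbsDiff))
})

# collapse a rule table to one cumulative shift per (m, kind, f, b); rules
# re-established for the same pattern act additively
aggregateRules <- function(rules) {
    r <- rules@rules
    key <- paste(r$mod_position, r$kind,
                 ifelse(is.na(r$pattern_position), "-", r$pattern_position),
                 ifelse(is.na(r$pattern_base), "-", r$pattern_base),
                 sep = "|")
    agg <- tapply(r$shift, key, sum)
    first <- r[!duplicated(key), c("mod_position", "kind",
                                   "pattern_position", "pattern_base")]
    first$shift <- as.numeric(agg[unique(key)])
    first$key <- unique(key)
    rownames(first) <- NULL
    first
}

#' Match a derived rule set against a ground truth
#'
#' Rules are matched on (modification position, kind, pattern position,
#' pattern base) after summing shifts of re-established identical patterns.
#' Reports the absolute shift error per matched rule and the rules present
#' in only one of the two sets.
#'
#' @param truth,derived \linkS4class{RuleSet}s with identical scheme and k.
#' @return A list with \code{matched} (data.frame with shift_truth,
#'   shift_derived, abs_error), \code{only_truth}, \code{only_derived}.
#' @export
ruleRecovery <- function(truth, derived) {
    if (truth@scheme@motif != derived@scheme@motif ||
        truth@scheme@modOffset != derived@scheme@modOffset ||
        truth@scheme@modCode != derived@scheme@modCode ||
        truth@k != derived@k)
        stop("rule sets have mismatched scheme or k")
    at <- aggregateRules(truth)
    ad <- aggregateRules(derived)
    hit <- match(at$key, ad$key)
    matched <- at[!is.na(hit), c("mod_position", "kind", "pattern_position",
                                 "pattern_base")]
    matched$shift_truth <- at$shift[!is.na(hit)]
    matched$shift_derived <- ad$shift[hit[!is.na(hit)]]
    matched$abs_error <- abs(matched$shift_truth - matched$shift_derived)
    rownames(matched) <- NULL
    drop_key <- function(x) x[, setdiff(names(x), "key"), drop = FALSE]
    list(matched = matched,
         only_truth = drop_key(at[is.na(hit), , drop = FALSE]),
         only_derived = drop_key(ad[!ad$key %in% at$key, , drop = FALSE]))
}

#' Median delta-C grouped by a neighboring base
#'
#' Groups delta-C records by the base found at (modification position +
#' offset), the view behind per-neighbor scatter coloring (e.g. the base
#' just before the motif, NNXMGN). Records whose offset position falls
#' outside the k-mer are dropped.
#'
#' @param delta A \linkS4class{DeltaTable}.
#' @param offset Signed integer offset from the modification position
#'   (|offset| >= 1).
#' @return \code{data.frame} with columns \code{base}, \code{median},
#'   \code{count}.
#' @export
neighborSummary <- function(delta, offset) {
    offset <- as.integer(offset)
    if (abs(offset) < 1L) stop("|offset| must be at least 1")
    r <- delta@records
    pos <- r$mod_position + offset
    ok <- pos >= 1L & pos <= delta@k
    base <- substr(r$kmer[ok], pos[ok], pos[ok])
    d <- r$delta[ok]
    bases <- sort(unique(base))
    data.frame(base = bases,
               median = vapply(bases, function(b) median(d[base == b]),
                               numeric(1L)),
               count = vapply(bases, function(b) sum(base == b), integer(1L)),
               row.names = NULL)
}
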