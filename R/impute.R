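#' Impute a modified k-mer model from a canonical model and delta-C rules
#'
#' Every enumerable modified k-mer receives the level of its canonical
#' counterpart plus, for each of its modification positions m, the position
#' rule for m and the shifts of all pattern rules (m, f, b) whose base b
#' appears at position f of the k-mer as written (a position holding a
#' modification code never matches a canonical-base pattern). Two modes:
#' \describe{
#'   \item{\code{"full"}}{rules determine all modified entries, overwriting
#'     trained values (denoising; the fully-imputed model).}
#'   \item{\code{"missing"}}{trained entries are copied verbatim from
#'     \code{trainedModel}; only the remaining modified k-mers are imputed
#'     (the missing-imputed model).}
#' }
#' Imputed entries keep the canonical counterpart's \code{level_stdv}; the
#' +1-inflated spread of placeholder entries is an untrained-value
#' convention, not a trained property.
#'
#' @param canonical Complete canonical \linkS4class{KmerModel}.
#' @param rules A \linkS4class{RuleSet} (scheme and k must match).
#' @param mode \code{"full"} or \code{"missing"}.
#' @param trainedModel For \code{mode = "missing"}: the partially trained
#'   modified \linkS4class{KmerModel}.
#' @param trained For \code{mode = "missing"}: character vector of trained
#'   k-mers to copy verbatim.
#' @param includeIncomplete Also emit incomplete-motif k-mers (no rules ever
#'   apply to them, so they keep canonical levels unless trained).
#' @param includeMulti Also emit multi-modification k-mers, imputed by
#'   summing the applicable rules of every modification position.
#' @return A \linkS4class{KmerModel} containing the canonical entries plus
#'   all enumerated modified entries.
#' @seealso [deriveRules()], [forwardApply()]
#' @export
imputeModel <- function(canonical, rules, mode = c("full", "missing"),
                        trainedModel = NULL, trained = NULL,
                        includeIncomplete = FALSE, includeMulti = FALSE) {
    mode <- match.arg(mode)
    k <- canonical@k
    scheme <- rules@scheme
    if (rules@k != k)
        stop("incompatible rule set: k = ", rules@k, " vs model k = ", k)
    if (scheme@modCode %in% canonical@alphabet)
        stop("incompatible input: canonical model already contains '",
             scheme@modCode, "'")
    if (mode == "missing" && (is.null(trainedModel) || is.null(trained)))
        stop("mode = 'missing' requires trainedModel and trained")
    targets <- enumerateModifiedKmers(k, scheme, includeIncomplete)
    if (includeMulti)
        targets <- c(targets,
                     enumerateMultiModifiedKmers(k, scheme, includeIncomplete))
    hit <- match(canonicalizeKmers(targets, scheme), canonical@entries$kmer)
    if (anyNA(hit))
        stop("incomplete input: canonical model must contain all 4^k k-mers")
    lvl <- canonical@entries$level_mean[hit]
    chars <- matrix(unlist(strsplit(targets, "")), ncol = k, byrow = TRUE)
    rl <- rules@rules
    for (j in seq_len(nrow(rl))) {
        mask <- chars[, rl$mod_position[j]] == scheme@modCode
        if (rl$kind[j] == "pattern")
            mask <- mask & chars[, rl$pattern_position[j]] == rl$pattern_base[j]
        lvl[mask] <- lvl[mask] + rl$shift[j]
    }
    newe <- canonical@entries[hit, , drop = FALSE]
    newe$kmer <- targets
    newe$level_mean <- lvl
    rownames(newe) <- NULL
    if (mode == "missing") {
        keep <- match(intersect(trained, targets), targets)
        src <- match(targets[keep], trainedModel@entries$kmer)
        if (anyNA(src))
            stop("trained k-mer(s) absent from trainedModel: ",
                 paste(head(targets[keep][is.na(src)], 5L), collapse = ", "))
        shared <- intersect(names(newe), names(trainedModel@entries))
        newe[keep, shared] <- trainedModel@entries[src, shared]
    }
    KmerModel(rbind(canonical@entries, newe),
              alphabet = c(canonical@alphabet, scheme@modCode),
              header = canonical@header)
}
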