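#' Simulate a random genome contig
#'
#' I.i.d. bases with P(G) = P(C) = gcFraction / 2 and the remainder split
#' equally between A and T.
#'
#' @param length Contig length (> 0).
#' @param gcFraction GC content in [0, 1] (default 0.5).
#' @param seed Integer seed.
#' @param name Contig name.
#' @return A \code{DNAStringSet} with one contig.
#' @examples
#' simulateGenome(100, seed = 1)
#' @export
simulateGenome <- function(length, gcFraction = 0.5, seed = 1L,
                           name = "synthetic_contig") {
    stopifnot(length > 0, gcFraction >= 0, gcFraction <= 1)
    set.seed(as.integer(seed))
    p <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
           G = gcFraction / 2, T = (1 - gcFraction) / 2)
    seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
                 collapse = "")
    stats::setNames(DNAStringSet(seq), name)
}

#' Simulate a complete canonical k-mer model
#'
#' All 4^k k-mers with \code{level_mean} uniform in \code{levelRange} and
#' \code{level_stdv} uniform in \code{stdvRange}; the defaults mimic the
#' scale of R9 pore models (roughly 60-130 pA).
#'
#' @param k k-mer length.
#' @param seed Integer seed.
#' @param levelRange,stdvRange Numeric length-2 ranges.
#' @return A \linkS4class{KmerModel}.
#' @export
simulateCanonicalModel <- function(k, seed = 1L, levelRange = c(60, 130),
                                   stdvRange = c(1.5, 4)) {
    stopifnot(k >= 1)
    set.seed(as.integer(seed))
    kmers <- allCanonicalKmers(as.integer(k))
    n <- length(kmers)
    KmerModel(data.frame(
        kmer = kmers,
        level_mean = runif(n, levelRange[1L], levelRange[2L]),
        level_stdv = runif(n, stdvRange[1L], stdvRange[2L])))
}

#' Simulate a ground-truth delta-C rule set
#'
#' One position rule per complete-motif modification position, with
#' distinct shifts, plus \code{nPatternRules} pattern rules drawn without
#' (m, f, b) collision from the positions outside each motif footprint.
#' Shift magnitudes are uniform in \code{shiftMagnitude} (never below
#' \code{minSeparation}) with random signs; the defaults echo the size of
#' shifts seen in real CpG tables (a few pA).
#'
#' @param scheme A \linkS4class{ModificationScheme}.
#' @param k k-mer length.
#' @param nPatternRules Number of pattern rules.
#' @param shiftMagnitude Length-2 range of |shift|.
#' @param minSeparation Lower bound on every |shift|.
#' @param distinctPositions Restrict pattern rules to distinct (m, f) pairs
#'   with at most two pattern positions per modification position. In this
#'   regime every candidate group's median of the other rules' contributions
#'   is exactly zero under full coverage, so median extraction identifies
#'   each shift exactly; with arbitrarily overlapping groups the additive
#'   decomposition is not unique (derivation then recovers the fitted
#'   delta-C function, not necessarily the same per-rule split).
#' @param seed Integer seed.
#' @return A \linkS4class{RuleSet}.
#' @export
simulateRuleSet <- function(scheme, k, nPatternRules = 10L,
                            shiftMagnitude = c(0.5, 5), minSeparation = 0.5,
                            distinctPositions = FALSE, seed = 1L) {
    set.seed(as.integer(seed))
    k <- as.integer(k)
    lo <- max(shiftMagnitude[1L], minSeparation)
    hi <- shiftMagnitude[2L]
    if (lo > hi) stop("infeasible shift range")
    ms <- completeMotifPositions(scheme, k)
    draw <- function(n) runif(n, lo, hi) * sample(c(-1, 1), n, replace = TRUE)
    combos <- do.call(rbind, lapply(ms, function(m) {
        fp <- motifFootprint(scheme, m)[[1L]]
        expand.grid(mod_position = m, pattern_position = setdiff(seq_len(k), fp),
                    pattern_base = CANONICAL_BASES, stringsAsFactors = FALSE)
    }))
    if (distinctPositions) {
        mf <- unique(combos[, c("mod_position", "pattern_position")])
        keep_mf <- do.call(rbind, lapply(split(mf, mf$mod_position),
            function(g) g[sample.int(nrow(g), min(2L, nrow(g))), ,
                          drop = FALSE]))
        combos <- combos[paste(combos$mod_position, combos$pattern_position)
                         %in% paste(keep_mf$mod_position,
                                    keep_mf$pattern_position), ,
                         drop = FALSE]
        # one base per retained (m, f)
        combos <- do.call(rbind, lapply(
            split(combos, paste(combos$mod_position,
                                combos$pattern_position)),
            function(g) g[sample.int(nrow(g), 1L), , drop = FALSE]))
        rownames(combos) <- NULL
    }
    if (nPatternRules > nrow(combos))
        stop("infeasible request: only ", nrow(combos),
             " distinct (m, f, b) combinations available",
             if (distinctPositions) " under distinctPositions")
    pos_rules <- data.frame(order = NA_integer_, mod_position = ms,
                            kind = "position",
                            pattern_position = NA_integer_,
                            pattern_base = NA_character_,
                            shift = draw(length(ms)))
    pick <- combos[sample.int(nrow(combos), nPatternRules), , drop = FALSE]
    pat_rules <- if (nPatternRules) data.frame(
        order = NA_integer_, mod_position = pick$mod_position,
        kind = "pattern", pattern_position = pick$pattern_position,
        pattern_base = pick$pattern_base, shift = draw(nPatternRules))
    rules <- rbind(pos_rules, pat_rules)
    # derivation order: per position, the position rule first, then its
    # pattern rules by decreasing |shift|
    rules <- rules[order(rules$mod_position, rules$kind != "position",
                         -abs(rules$shift)), , drop = FALSE]
    rules$order <- seq_len(nrow(rules))
    RuleSet(rules, scheme, k)
}

#' Forward-apply delta-C rules to a canonical model
#'
#' Direct per-k-mer summation of all applicable rule shifts added to the
#' canonical counterpart's level. This is a deliberately naive, independent
#' implementation of the same arithmetic as \code{\link{imputeModel}}
#' (mode \code{"full"}) and serves as its cross-check in tests.
#'
#' @param canonical Complete canonical \linkS4class{KmerModel}.
#' @param rules A \linkS4class{RuleSet}.
#' @param includeIncomplete,includeMulti Which modified k-mers to emit, as
#'   in \code{\link{imputeModel}}.
#' @return A \linkS4class{KmerModel} with canonical plus modified entries.
#' @export
forwardApply <- function(canonical, rules, includeIncomplete = FALSE,
                         includeMulti = FALSE) {
    scheme <- rules@scheme
    k <- canonical@k
    targets <- enumerateModifiedKmers(k, scheme, includeIncomplete)
    if (includeMulti)
        targets <- c(targets,
                     enumerateMultiModifiedKmers(k, scheme, includeIncomplete))
    rl <- rules@rules
    lvl <- vapply(targets, function(x) {
        chars <- strsplit(x, "")[[1L]]
        v <- levelMeans(canonical, canonicalizeKmers(x, scheme))[[1L]]
        for (m in which(chars == scheme@modCode)) {
            for (j in seq_len(nrow(rl))) {
                if (rl$mod_position[j] != m) next
                applies <- if (rl$kind[j] == "position") TRUE
                           else chars[rl$pattern_position[j]] == rl$pattern_base[j]
                if (applies) v <- v + rl$shift[j]
            }
        }
        v
    }, numeric(1L))
    hit <- match(canonicalizeKmers(targets, scheme), canonical@entries$kmer)
    newe <- canonical@entries[hit, , drop = FALSE]
    newe$kmer <- targets
    newe$level_mean <- unname(lvl)
    rownames(newe) <- NULL
    KmerModel(rbind(canonical@entries, newe),
              alphabet = c(canonical@alphabet, scheme@modCode),
              header = canonical@header)
}

#' Add Gaussian noise to expected levels
#'
#' Perturbs \code{level_mean} with i.i.d. N(0, sd^2) noise. With a scheme
#' given, only modified entries (those containing the modification code)
#' are perturbed - the usual simulation setup, where the canonical table is
#' treated as known and only modified levels carry training noise.
#'
#' @param model A \linkS4class{KmerModel}.
#' @param sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param scheme Optional \linkS4class{ModificationScheme}; restricts noise
#'   to modified entries.
#' @param kmers Optional character vector; restricts noise to these k-mers
#'   (e.g. the trained inventory).
#' @return The perturbed \linkS4class{KmerModel}.
#' @export
addNoise <- function(model, sd, seed = 1L, scheme = NULL, kmers = NULL) {
    stopifnot(sd >= 0)
    if (sd == 0) return(model)
    set.seed(as.integer(seed))
    e <- model@entries
    which_rows <- if (!is.null(kmers)) which(e$kmer %in% kmers)
                  else if (!is.null(scheme))
                      grep(scheme@modCode, e$kmer, fixed = TRUE)
                  else seq_len(nrow(e))
    e$level_mean[which_rows] <- e$level_mean[which_rows] +
        rnorm(length(which_rows), 0, sd)
    methods::initialize(model, entries = e)
}

#' Sample a trained k-mer inventory
#'
#' \code{mode = "kmer"}: uniform sample of the complete-motif modified
#' k-mers. \code{mode = "site"}: the k-mers covered by a greedy training
#' site selection on a genome (\code{\link{selectTrainingSites}}), the
#' setup that mirrors sampling motif sites from a reference.
#'
#' @param scheme A \linkS4class{ModificationScheme}.
#' @param k k-mer length.
#' @param fraction Target fraction of the 4^(k-|motif|) x (k-|motif|+1)
#'   complete-motif k-mers, in (0, 1].
#' @param mode \code{"kmer"} or \code{"site"}.
#' @param seed Integer seed.
#' @param genome Genome for \code{mode = "site"}.
#' @param bothStrands Passed to \code{\link{selectTrainingSites}}.
#' @return Character vector of trained modified k-mers.
#' @export
holdoutKmers <- function(scheme, k, fraction, mode = c("kmer", "site"),
                         seed = 1L, genome = NULL, bothStrands = TRUE) {
    mode <- match.arg(mode)
    stopifnot(fraction > 0, fraction <= 1)
    if (mode == "kmer") {
        universe <- enumerateModifiedKmers(k, scheme, FALSE)
        set.seed(as.integer(seed))
        sort(sample(universe, round(fraction * length(universe))),
             method = "radix")
    } else {
        if (is.null(genome)) stop("mode = 'site' requires a genome")
        coveredKmers(selectTrainingSites(genome, scheme, k, fraction,
                                         seed = seed,
                                         bothStrands = bothStrands))
    }
}

#' Simulate a fully known modification scenario
#'
#' Builds, from one master seed, a canonical model, a ground-truth rule
#' set, the clean forward-applied modified model, a noisy variant (training
#' noise on the trained modified levels only) and a trained k-mer
#' inventory.
#'
#' @param scheme A \linkS4class{ModificationScheme}.
#' @param k k-mer length.
#' @param nPatternRules Ground-truth pattern rule count.
#' @param noiseSd Gaussian noise sd on trained modified levels.
#' @param trainedFraction Fraction of complete-motif k-mers trained.
#' @param holdoutMode \code{"kmer"} or \code{"site"}.
#' @param genome Genome for site-based holdout.
#' @param seed Master seed; sub-seeds are derived from it.
#' @param ... Passed to \code{\link{simulateRuleSet}}.
#' @return A \linkS4class{SyntheticTruth}.
#' @export
simulateTruth <- function(scheme, k = 6L, nPatternRules = 10L, noiseSd = 0,
                          trainedFraction = 1, holdoutMode = c("kmer", "site"),
                          genome = NULL, seed = 1L, ...) {
    holdoutMode <- match.arg(holdoutMode)
    seed <- as.integer(seed)
    sub <- function(i) (seed * 7L + i) %% 2147483647L
    canonical <- simulateCanonicalModel(k, seed = sub(1L))
    rules <- simulateRuleSet(scheme, k, nPatternRules, seed = sub(2L), ...)
    clean <- forwardApply(canonical, rules)
    trained <- if (trainedFraction >= 1)
        enumerateModifiedKmers(k, scheme, FALSE)
    else holdoutKmers(scheme, k, trainedFraction, mode = holdoutMode,
                      seed = sub(4L), genome = genome)
    # training noise touches the trained modified levels only; untrained
    # entries are placeholders a real partial table would not have trained
    noisy <- addNoise(clean, noiseSd, seed = sub(3L), kmers = trained)
    new("SyntheticTruth", canonical = canonical, rules = rules,
        modifiedClean = clean, modifiedNoisy = noisy,
        noiseSd = as.numeric(noiseSd), trained = trained, seed = seed)
}

#' @describeIn SyntheticTruth Ground-truth rule set.
#' @param truth A \linkS4class{SyntheticTruth}.
#' @export
truthRules <- function(truth) truth@rules

#' @describeIn SyntheticTruth Canonical model.
#' @export
truthCanonical <- function(truth) truth@canonical

#' @describeIn SyntheticTruth Clean / noisy modified models.
#' @export
truthModified <- function(truth, noisy = FALSE)
    if (noisy) truth@modifiedNoisy else truth@modifiedClean

#' @describeIn SyntheticTruth Trained k-mer inventory.
#' @export
trainedKmers <- function(truth) truth@trained

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth: k = ", object@canonical@k, ", ",
        nRules(object@rules), " rules, noise sd ", object@noiseSd,
        ", ", length(object@trained), " trained k-mers (seed ",
        object@seed, ")\n", sep = "")
})
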