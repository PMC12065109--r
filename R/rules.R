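#' Construct a RuleSet from a rules table
#'
#' @param rules \code{data.frame} with columns \code{order},
#'   \code{mod_position}, \code{kind}, \code{pattern_position},
#'   \code{pattern_base}, \code{shift}.
#' @param scheme A \linkS4class{ModificationScheme}.
#' @param k k-mer length.
#' @return A \linkS4class{RuleSet}.
#' @export
RuleSet <- function(rules, scheme, k) {
    rules <- as.data.frame(rules)
    rules$order <- as.integer(rules$order)
    rules$mod_position <- as.integer(rules$mod_position)
    rules$kind <- as.character(rules$kind)
    rules$pattern_position <- as.integer(rules$pattern_position)
    rules$pattern_base <- as.character(rules$pattern_base)
    rules$shift <- as.numeric(rules$shift)
    rules <- rules[order(rules$order), , drop = FALSE]
    rownames(rules) <- NULL
    new("RuleSet", scheme = scheme, k = as.integer(k), rules = rules)
}

#' @describeIn RuleSet The ordered rules \code{data.frame}.
#' @param rules A \linkS4class{RuleSet}.
#' @export
ruleTable <- function(rules) rules@rules

#' @describeIn RuleSet Number of rules (position + pattern).
#' @export
nRules <- function(rules) nrow(rules@rules)

setMethod("show", "RuleSet", function(object) {
    r <- object@rules
    cat("RuleSet: ", sum(r$kind == "position"), " position rule(s), ",
        sum(r$kind == "pattern"), " pattern rule(s) (k = ", object@k,
        ", motif ", object@scheme@motif, ")\n", sep = "")
    if (nrow(r)) {
        ps <- patternStrings(object)
        n <- min(nrow(r), 10L)
        for (i in seq_len(n))
            cat(sprintf("  %3d  %s  %+.3f\n", r$order[i], ps[i], r$shift[i]))
        if (nrow(r) > n) cat("  ... and", nrow(r) - n, "more\n")
    }
})

#' Render rules as pattern strings
#'
#' Each rule becomes a k-character string with \code{N} at free positions,
#' the modification code plus motif at the modification position, and the
#' pattern base at the pattern position, e.g. \code{NNTMGN} for a CpG rule
#' with the modification at position 4 and a T at position 3.
#'
#' @param rules A \linkS4class{RuleSet}.
#' @return Character vector, one pattern per rule.
#' @export
patternStrings <- function(rules) {
    r <- rules@rules
    scheme <- rules@scheme
    k <- rules@k
    mchars <- strsplit(scheme@motif, "")[[1L]]
    mchars[scheme@modOffset + 1L] <- scheme@modCode
    vapply(seq_len(nrow(r)), function(i) {
        chars <- rep("N", k)
        fp <- motifFootprint(scheme, r$mod_position[i])[[1L]]
        keep <- fp >= 1L & fp <= k
        chars[fp[keep]] <- mchars[keep]
        if (r$kind[i] == "pattern")
            chars[r$pattern_position[i]] <- r$pattern_base[i]
        paste(chars, collapse = "")
    }, character(1L))
}

# candidate pattern medians for one modification position, given the char
# matrix of that position's training k-mers and current residuals
candidateMedians <- function(chars, resid, candPos, minGroupSize) {
    out <- data.frame(pattern_position = integer(0),
                      pattern_base = character(0),
                      med = numeric(0), n = integer(0))
    for (f in candPos) {
        for (b in CANONICAL_BASES) {
            g <- chars[, f] == b
            n <- sum(g)
            if (n >= minGroupSize)
                out <- rbind(out, data.frame(
                    pattern_position = f, pattern_base = b,
                    med = median(resid[g]), n = n))
        }
    }
    out
}

#' Derive an ordered delta-C rule set from a delta table
#'
#' For each modification position m present in the training data the
#' position rule is the median delta-C of all k-mers modified at m;
#' residuals are the deltas minus that shift. Then, iteratively, every
#' candidate pattern (a base b at a position f outside the motif footprint,
#' with at least \code{minGroupSize} matching training k-mers) is scored by
#' the median residual of its matching k-mers; the pattern with the largest
#' absolute median is established as a rule (ties: smallest f, then
#' alphabetical b), its median is subtracted from the residuals of the
#' matching k-mers only, and the scan repeats until no candidate median
#' exceeds the stopping threshold \code{r}.
#'
#' @param delta A non-empty \linkS4class{DeltaTable}.
#' @param r Stopping threshold in model units (> 0). The default 0.01 suits
#'   pA-scale tables; rescaled tables need a rescaled threshold.
#' @param maxIterationsPerPosition Safety cap on pattern extractions per
#'   modification position.
#' @param minGroupSize Minimum matching training k-mers for a candidate.
#' @return A \linkS4class{RuleSet}.
#' @seealso [imputeModel()], [summarizeByPosition()], [ruleResidualScan()]
#' @export
deriveRules <- function(delta, r = 0.01, maxIterationsPerPosition = 1000L,
                        minGroupSize = 1L) {
    stopifnot(r > 0)
    rec <- delta@records
    if (!nrow(rec)) stop("empty delta table")
    k <- delta@k
    scheme <- delta@scheme
    allchars <- matrix(unlist(strsplit(rec$kmer, "")), ncol = k, byrow = TRUE)
    rows <- list()
    ord <- 0L
    for (m in sort(unique(rec$mod_position))) {
        idx <- which(rec$mod_position == m)
        chars <- allchars[idx, , drop = FALSE]
        shift <- median(rec$delta[idx])
        resid <- rec$delta[idx] - shift
        ord <- ord + 1L
        rows[[length(rows) + 1L]] <- data.frame(
            order = ord, mod_position = m, kind = "position",
            pattern_position = NA_integer_, pattern_base = NA_character_,
            shift = shift)
        fp <- motifFootprint(scheme, m)[[1L]]
        candPos <- setdiff(seq_len(k), fp)
        iter <- 0L
        repeat {
            cand <- candidateMedians(chars, resid, candPos, minGroupSize)
            if (!nrow(cand)) break
            best <- cand[order(-abs(cand$med), cand$pattern_position,
                               cand$pattern_base), ][1L, ]
            if (abs(best$med) <= r) break
            iter <- iter + 1L
            if (iter > maxIterationsPerPosition)
                stop("rule derivation did not converge at modification ",
                     "position ", m, "; pattern (", best$pattern_position,
                     ", ", best$pattern_base, ") still shifts by ",
                     signif(best$med, 4L),
                     " - raise r or maxIterationsPerPosition")
            ord <- ord + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                order = ord, mod_position = m, kind = "pattern",
                pattern_position = best$pattern_position,
                pattern_base = best$pattern_base, shift = best$med)
            g <- chars[, best$pattern_position] == best$pattern_base
            resid[g] <- resid[g] - best$med
        }
    }
    RuleSet(do.call(rbind, rows), scheme, k)
}

#' Re-scan residuals against a rule set (termination certificate)
#'
#' Applies a rule set back to the delta table it was derived from and
#' reports, per modification position, the largest absolute candidate
#' median left in the residuals. After \code{\link{deriveRules}} every value
#' is at most the stopping threshold r.
#'
#' @param delta The \linkS4class{DeltaTable} used for derivation.
#' @param rules The derived \linkS4class{RuleSet}.
#' @param minGroupSize Candidate group-size floor used at derivation.
#' @return \code{data.frame} with columns \code{mod_position} and
#'   \code{max_abs_median}.
#' @export
ruleResidualScan <- function(delta, rules, minGroupSize = 1L) {
    rec <- delta@records
    k <- delta@k
    scheme <- delta@scheme
    rl <- rules@rules
    allchars <- matrix(unlist(strsplit(rec$kmer, "")), ncol = k, byrow = TRUE)
    ms <- sort(unique(rec$mod_position))
    out <- data.frame(mod_position = ms, max_abs_median = NA_real_)
    for (i in seq_along(ms)) {
        m <- ms[i]
        idx <- which(rec$mod_position == m)
        chars <- allchars[idx, , drop = FALSE]
        resid <- rec$delta[idx]
        for (j in which(rl$mod_position == m)) {
            if (rl$kind[j] == "position") resid <- resid - rl$shift[j]
            else {
                g <- chars[, rl$pattern_position[j]] == rl$pattern_base[j]
                resid[g] <- resid[g] - rl$shift[j]
            }
        }
        fp <- motifFootprint(scheme, m)[[1L]]
        cand <- candidateMedians(chars, resid, setdiff(seq_len(k), fp),
                                 minGroupSize)
        out$max_abs_median[i] <- if (nrow(cand)) max(abs(cand$med)) else 0
    }
    out
}

#' Write a rule set as TSV
#'
#' Emits scheme and k metadata as \code{#key=value} lines, then one row per
#' rule with columns \code{order}, \code{kind}, \code{pattern} (the
#' \code{\link{patternStrings}} rendering) and \code{shift} (full
#' precision, so \code{readRules} round-trips exactly).
#'
#' @param rules A \linkS4class{RuleSet}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeRules <- function(rules, path) {
    r <- rules@rules
    meta <- c(sprintf("#k=%d", rules@k),
              sprintf("#motif=%s", rules@scheme@motif),
              sprintf("#mod_offset=%d", rules@scheme@modOffset),
              sprintf("#mod_code=%s", rules@scheme@modCode))
    lines <- c(meta, "order\tkind\tpattern\tshift",
               if (nrow(r)) sprintf("%d\t%s\t%s\t%.17g", r$order, r$kind,
                                    patternStrings(rules), r$shift))
    writeLines(lines, path)
    invisible(path)
}

#' Read a rule set written by \code{writeRules}
#'
#' @param path Path to a rule TSV file.
#' @return A \linkS4class{RuleSet}.
#' @export
readRules <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    meta_lines <- lines[startsWith(lines, "#")]
    meta <- list()
    for (ln in sub("^#", "", meta_lines)) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
        if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
    }
    need <- c("k", "motif", "mod_offset", "mod_code")
    if (!all(need %in% names(meta)))
        stop("rule file lacks #k/#motif/#mod_offset/#mod_code metadata")
    k <- as.integer(meta$k)
    scheme <- ModificationScheme(meta$motif, as.integer(meta$mod_offset),
                                 meta$mod_code)
    body <- lines[!startsWith(lines, "#")]
    body <- body[-1L]  # column header
    if (!length(body))
        return(RuleSet(data.frame(order = integer(0),
                                  mod_position = integer(0),
                                  kind = character(0),
                                  pattern_position = integer(0),
                                  pattern_base = character(0),
                                  shift = numeric(0)), scheme, k))
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) != 4L))
        stop("malformed rule line: '", body[which(lengths(fields) != 4L)[1L]],
             "'")
    m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
    parsed <- lapply(m[, 3L], parsePatternString, scheme = scheme, k = k)
    rules <- data.frame(
        order = as.integer(m[, 1L]),
        mod_position = vapply(parsed, `[[`, integer(1L), "mod_position"),
        kind = m[, 2L],
        pattern_position = vapply(parsed, `[[`, integer(1L),
                                  "pattern_position"),
        pattern_base = vapply(parsed, `[[`, character(1L), "pattern_base"),
        shift = as.numeric(m[, 4L]))
    if (anyNA(rules$shift)) stop("non-numeric shift in rule file")
    RuleSet(rules, scheme, k)
}

# decompose "NNTMGN" into mod position and optional (pattern pos, base)
parsePatternString <- function(pattern, scheme, k) {
    if (nchar(pattern) != k)
        stop("malformed pattern string '", pattern, "': length != k")
    chars <- strsplit(pattern, "")[[1L]]
    at <- which(chars == scheme@modCode)
    if (length(at) != 1L)
        stop("malformed pattern string '", pattern,
             "': need exactly one modification code")
    m <- at
    fp <- motifFootprint(scheme, m)[[1L]]
    fp <- fp[fp >= 1L & fp <= k]
    rest <- setdiff(which(chars != "N"), fp)
    if (length(rest) > 1L)
        stop("malformed pattern string '", pattern,
             "': more than one pattern base")
    if (length(rest) == 1L && !chars[rest] %in% CANONICAL_BASES)
        stop("malformed pattern string '", pattern,
             "': pattern base must be A/C/G/T")
    list(mod_position = m,
         pattern_position = if (length(rest)) rest else NA_integer_,
         pattern_base = if (length(rest)) chars[rest] else NA_character_)
}
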