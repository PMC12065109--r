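# Placements of the modification within a k-mer window: each placement is a
# list(m = mod position, pos = in-window fixed positions, chars = the fixed
# characters, i.e. the (possibly truncated) motif with the mod code at the
# modified base).
modPlacements <- function(k, scheme, includeIncomplete = FALSE) {
    w <- nchar(scheme@motif)
    if (k < w) stop("invalid parameter: k < motif length")
    mchars <- strsplit(scheme@motif, "")[[1L]]
    mchars[scheme@modOffset + 1L] <- scheme@modCode
    one <- function(m) {
        fp <- seq.int(m - scheme@modOffset, m - scheme@modOffset + w - 1L)
        keep <- fp >= 1L & fp <= k
        list(m = m, pos = fp[keep], chars = mchars[keep])
    }
    ms <- completeMotifPositions(scheme, k)
    pl <- lapply(ms, one)
    if (includeIncomplete)
        pl <- c(pl, lapply(setdiff(seq_len(k), ms), one))
    pl
}

# all k-mers realizing a set of fixed (position, char) assignments, free
# positions ranging over ACGT
fillPlacement <- function(k, pos, chars) {
    free <- setdiff(seq_len(k), pos)
    n <- 4L^length(free)
    cols <- vector("list", k)
    for (i in seq_along(pos)) cols[[pos[i]]] <- rep(chars[i], n)
    if (length(free)) {
        g <- do.call(expand.grid,
                     c(rep(list(CANONICAL_BASES), length(free)),
                       stringsAsFactors = FALSE))
        for (i in seq_along(free)) cols[[free[i]]] <- g[[i]]
    }
    do.call(paste0, cols)
}

#' Enumerate single-modification k-mers for a scheme
#'
#' All k-mers over ACGT plus the modification code that contain exactly one
#' modification code. By default the motif must sit completely inside the
#' k-mer window; with \code{includeIncomplete = TRUE}, placements where the
#' motif runs off the window edge (e.g. \code{NNNNNM} for CpG, where the G
#' falls outside) are also generated. For a CpG scheme at k = 6 the
#' complete-motif set has 1280 k-mers and grows to 2304 with incomplete
#' motifs included.
#'
#' @param k k-mer length (at least the motif length).
#' @param scheme A \linkS4class{ModificationScheme}.
#' @param includeIncomplete Also allow the motif to run off the window edge.
#' @return Sorted character vector of modified k-mers.
#' @examples
#' length(enumerateModifiedKmers(6, ModificationScheme("CG", 0, "M")))  # 1280
#' enumerateModifiedKmers(2, ModificationScheme("CG", 0, "M"))          # "MG"
#' @export
enumerateModifiedKmers <- function(k, scheme, includeIncomplete = FALSE) {
    k <- as.integer(k)
    pl <- modPlacements(k, scheme, includeIncomplete)
    out <- unlist(lapply(pl, function(p) fillPlacement(k, p$pos, p$chars)))
    sort(unique(out), method = "radix")
}

# k-mers with >= minMods modifications; compatible placement subsets are
# those whose fixed characters agree on shared positions
enumerateMultiModifiedKmers <- function(k, scheme, includeIncomplete = FALSE,
                                        minMods = 2L) {
    pl <- modPlacements(k, scheme, includeIncomplete)
    n <- length(pl)
    out <- character(0)
    for (bits in seq_len(2L^n - 1L)) {
        sel <- pl[bitwAnd(bits, 2L^(seq_len(n) - 1L)) > 0L]
        if (length(sel) < minMods) next
        pos <- unlist(lapply(sel, `[[`, "pos"))
        chars <- unlist(lapply(sel, `[[`, "chars"))
        first <- !duplicated(pos)
        agree <- vapply(seq_along(pos),
                        function(i) chars[i] == chars[match(pos[i], pos)],
                        logical(1L))
        if (!all(agree)) next
        out <- c(out, fillPlacement(k, pos[first], chars[first]))
    }
    # subsets overlapping in free positions can duplicate strings; also a
    # "free" base may coincide with another placement's motif, so keep only
    # strings with the right modification count
    out <- unique(out)
    nm <- nchar(out) - nchar(gsub(scheme@modCode, "", out, fixed = TRUE))
    sort(out[nm >= minMods], method = "radix")
}

#' Expand a canonical model's alphabet with a modification code
#'
#' Adds modified k-mer entries to a complete canonical model: each new entry
#' copies \code{level_mean} from its canonical counterpart (modification
#' code replaced by the canonical base) and copies \code{level_stdv}
#' increased by \code{stdvIncrement} (default 1), the Nanopolish convention
#' marking untrained placeholder entries. By default only single-modification,
#' complete-motif k-mers are generated.
#'
#' @param canonical A complete canonical \linkS4class{KmerModel} (all 4^k
#'   ACGT k-mers).
#' @param scheme A \linkS4class{ModificationScheme}; its code must not be in
#'   the model's alphabet yet.
#' @param stdvIncrement Added to \code{level_stdv} of every new entry.
#' @param includeIncomplete Also generate incomplete-motif k-mers.
#' @param includeMulti Also generate k-mers with more than one modification.
#' @return A \linkS4class{KmerModel} over the expanded alphabet.
#' @examples
#' cm <- simulateCanonicalModel(2, seed = 1)
#' em <- expandAlphabet(cm, ModificationScheme("CG", 0, "M"))
#' modelEntries(em)[modelKmers(em) == "MG", ]
#' @export
expandAlphabet <- function(canonical, scheme, stdvIncrement = 1.0,
                           includeIncomplete = FALSE, includeMulti = FALSE) {
    k <- canonical@k
    if (scheme@modCode %in% canonical@alphabet)
        stop("modification code '", scheme@modCode,
             "' already in model alphabet")
    if (nrow(canonical@entries) < 4L^k ||
        !all(allCanonicalKmers(k) %in% canonical@entries$kmer))
        stop("incomplete input: canonical model must contain all 4^k k-mers")
    targets <- enumerateModifiedKmers(k, scheme, includeIncomplete)
    if (includeMulti)
        targets <- c(targets,
                     enumerateMultiModifiedKmers(k, scheme, includeIncomplete))
    hit <- match(canonicalizeKmers(targets, scheme), canonical@entries$kmer)
    if (anyNA(hit))
        stop("incomplete input: missing canonical counterpart(s)")
    newe <- canonical@entries[hit, , drop = FALSE]
    newe$kmer <- targets
    newe$level_stdv <- newe$level_stdv + stdvIncrement
    rownames(newe) <- NULL
    KmerModel(rbind(canonical@entries, newe),
              alphabet = c(canonical@alphabet, scheme@modCode),
              header = canonical@header)
}
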