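#' @import methods
#' @importFrom stats median rnorm runif cor
#' @importFrom utils read.table write.table head
#' @importClassesFrom GenomicRanges GRanges
NULL

CANONICAL_BASES <- c("A", "C", "G", "T")

#' ModificationScheme: where a base modification sits in its sequence motif
#'
#' Describes a base modification by the canonical motif it occurs in
#' (e.g. \code{"CG"} for CpG methylation), the 0-based offset of the base
#' within the motif that becomes modified, and the single-character
#' modification code used in modified k-mer strings (e.g. \code{"M"}).
#'
#' @slot motif Character scalar over ACGT.
#' @slot modOffset Integer, 0-based index into \code{motif} of the modified
#'   base.
#' @slot modCode Single character not in ACGT.
#'
#' @examples
#' ModificationScheme("CG", 0L, "M")   # 5mCpG
#' ModificationScheme("GC", 1L, "M")   # 5mGpC: the modified C follows the G
#' @export
setClass("ModificationScheme",
    representation(motif = "character", modOffset = "integer",
                   modCode = "character"))

setValidity("ModificationScheme", function(object) {
    msg <- character()
    if (length(object@motif) != 1L || nchar(object@motif) < 1L)
        msg <- c(msg, "'motif' must be a single non-empty string")
    else if (!all(strsplit(object@motif, "")[[1L]] %in% CANONICAL_BASES))
        msg <- c(msg, "'motif' must use only A, C, G, T")
    if (length(object@modOffset) != 1L || is.na(object@modOffset) ||
        object@modOffset < 0L || object@modOffset >= nchar(object@motif))
        msg <- c(msg, "'modOffset' must be a 0-based index into 'motif'")
    if (length(object@modCode) != 1L || nchar(object@modCode) != 1L ||
        object@modCode %in% CANONICAL_BASES)
        msg <- c(msg, "'modCode' must be a single character outside ACGT")
    if (length(msg)) msg else TRUE
})

#' KmerModel: a k-mer to expected-current-level table
#'
#' In-memory representation of a Nanopolish/f5c-style pore model: one row per
#' k-mer with the expected current level (\code{level_mean}), its spread
#' (\code{level_stdv}) and, when present, event-duration noise columns
#' (\code{sd_mean}, \code{sd_stdv}). Header metadata lines are kept verbatim
#' so a read/write round trip reproduces the file.
#'
#' @slot k Integer k-mer length.
#' @slot alphabet Character vector of allowed k-mer characters (ACGT plus
#'   zero or more modification codes).
#' @slot entries A \code{data.frame} with columns \code{kmer},
#'   \code{level_mean}, \code{level_stdv} and optionally \code{sd_mean},
#'   \code{sd_stdv} plus any extra columns carried along from a file.
#' @slot header Character vector: verbatim \code{#}-prefixed metadata lines
#'   plus the column-header line, in file order.
#' @export
setClass("KmerModel",
    representation(k = "integer", alphabet = "character",
                   entries = "data.frame", header = "character"))

setValidity("KmerModel", function(object) {
    msg <- character()
    e <- object@entries
    if (!all(c("kmer", "level_mean", "level_stdv") %in% names(e)))
        return("'entries' needs columns kmer, level_mean, level_stdv")
    if (nrow(e)) {
        if (any(nchar(e$kmer) != object@k))
            msg <- c(msg, sprintf("all k-mers must have length %d", object@k))
        if (anyDuplicated(e$kmer))
            msg <- c(msg, "k-mers must be unique")
        used <- unique(strsplit(paste(e$kmer, collapse = ""), "")[[1L]])
        if (!all(used %in% object@alphabet))
            msg <- c(msg, sprintf("k-mers use characters outside alphabet: %s",
                     paste(setdiff(used, object@alphabet), collapse = ",")))
        if (any(!is.finite(e$level_mean)))
            msg <- c(msg, "level_mean must be finite")
        if (any(e$level_stdv <= 0))
            msg <- c(msg, "level_stdv must be > 0")
    }
    if (length(msg)) msg else TRUE
})

#' DeltaTable: observed modification-induced current shifts
#'
#' One record per trained modified k-mer holding the difference
#' delta-C = modified level_mean minus the canonical counterpart's
#' level_mean (the counterpart being the k-mer with the modification code
#' replaced by its canonical base).
#'
#' @slot scheme A \linkS4class{ModificationScheme}.
#' @slot k Integer k-mer length.
#' @slot records A \code{data.frame} with columns \code{kmer},
#'   \code{mod_position} (1-based position of the modification code) and
#'   \code{delta}.
#' @export
setClass("DeltaTable",
    representation(scheme = "ModificationScheme", k = "integer",
                   records = "data.frame"))

setValidity("DeltaTable", function(object) {
    r <- object@records
    if (!all(c("kmer", "mod_position", "delta") %in% names(r)))
        return("'records' needs columns kmer, mod_position, delta")
    if (nrow(r) && anyDuplicated(r$kmer)) return("k-mers must be unique")
    if (nrow(r) && any(nchar(r$kmer) != object@k))
        return(sprintf("all k-mers must have length %d", object@k))
    TRUE
})

#' RuleSet: an ordered set of delta-C rules
#'
#' The ordered additive rules summarizing a \linkS4class{DeltaTable}. Each
#' modification position m carries one position rule (the median shift of
#' all k-mers modified at m) followed by pattern rules: a base b at a
#' position f outside the motif footprint, with the median residual shift h
#' observed when b co-occurs with the modification.
#'
#' @slot scheme A \linkS4class{ModificationScheme}.
#' @slot k Integer k-mer length.
#' @slot rules A \code{data.frame} with columns \code{order},
#'   \code{mod_position}, \code{kind} ("position" or "pattern"),
#'   \code{pattern_position}, \code{pattern_base} (NA for position rules)
#'   and \code{shift}.
#' @export
setClass("RuleSet",
    representation(scheme = "ModificationScheme", k = "integer",
                   rules = "data.frame"))

setValidity("RuleSet", function(object) {
    r <- object@rules
    need <- c("order", "mod_position", "kind", "pattern_position",
              "pattern_base", "shift")
    if (!all(need %in% names(r)))
        return(paste("'rules' needs columns", paste(need, collapse = ", ")))
    if (nrow(r)) {
        if (!all(r$kind %in% c("position", "pattern")))
            return("rule kind must be 'position' or 'pattern'")
        pat <- r$kind == "pattern"
        if (any(is.na(r$pattern_position[pat])) ||
            any(is.na(r$pattern_base[pat])))
            return("pattern rules need pattern_position and pattern_base")
        if (!all(r$pattern_base[pat] %in% CANONICAL_BASES))
            return("pattern_base must be one of A, C, G, T")
        fp <- motifFootprint(object@scheme, r$mod_position[pat])
        if (any(mapply(function(f, i) f %in% fp[[i]],
                       r$pattern_position[pat], seq_len(sum(pat)))))
            return("pattern_position must lie outside the motif footprint")
        if (anyDuplicated(r$mod_position[r$kind == "position"]))
            return("at most one position rule per modification position")
    }
    TRUE
})

#' SiteSelection: training motif sites and the k-mers they cover
#'
#' The result of greedy, seeded training-site selection on a reference
#' genome: the accepted sites in acceptance order, the unique modified
#' k-mers they contribute, and the achieved fraction of all possible
#' complete-motif single-modification k-mers.
#'
#' @slot sites A \code{GRanges} of accepted sites (width-1 ranges at the
#'   modified base, forward coordinates, with strand).
#' @slot coveredKmers Character vector of modified k-mers covered.
#' @slot targetFraction,achievedFraction Numeric fractions in (0, 1].
#' @slot seed Integer seed that produced the site ordering.
#' @slot scheme A \linkS4class{ModificationScheme}.
#' @slot k Integer k-mer length.
#' @export
setClass("SiteSelection",
    representation(sites = "GRanges", coveredKmers = "character",
                   targetFraction = "numeric", achievedFraction = "numeric",
                   seed = "integer", scheme = "ModificationScheme",
                   k = "integer"))

#' ComparisonReport: summary statistics of a model-vs-model comparison
#'
#' @slot n Integer number of k-mer pairs compared.
#' @slot pearson Pearson correlation of the paired values (NA when n < 2).
#' @slot rmse Root-mean-square difference.
#' @slot maxAbsDiff Largest absolute difference.
#' @slot subset Label of the compared subset ("all", "trained", "imputed").
#' @export
setClass("ComparisonReport",
    representation(n = "integer", pearson = "numeric", rmse = "numeric",
                   maxAbsDiff = "numeric", subset = "character"))

#' SyntheticTruth: a fully known simulation scenario
#'
#' Bundles the objects a simulated experiment needs: a canonical model, the
#' ground-truth rule set, the clean forward-applied modified model, a noisy
#' trained variant, and the trained k-mer inventory.
#'
#' @slot canonical,modifiedClean,modifiedNoisy \linkS4class{KmerModel}s.
#' @slot rules Ground-truth \linkS4class{RuleSet}.
#' @slot noiseSd Gaussian noise standard deviation applied to trained levels.
#' @slot trained Character vector of trained modified k-mers.
#' @slot seed Master seed.
#' @export
setClass("SyntheticTruth",
    representation(canonical = "KmerModel", rules = "RuleSet",
                   modifiedClean = "KmerModel", modifiedNoisy = "KmerModel",
                   noiseSd = "numeric", trained = "character",
                   seed = "integer"))
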