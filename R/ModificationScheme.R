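#' Create a ModificationScheme
#'
#' @param motif Canonical motif string over ACGT, e.g. \code{"CG"}.
#' @param modOffset 0-based offset into \code{motif} of the modified base.
#' @param modCode Single-character modification code, not in ACGT.
#' @return A \linkS4class{ModificationScheme}.
#' @examples
#' cpg <- ModificationScheme("CG", 0, "M")
#' canonicalBase(cpg)
#' @export
ModificationScheme <- function(motif, modOffset = 0L, modCode = "M") {
    new("ModificationScheme", motif = as.character(motif),
        modOffset = as.integer(modOffset), modCode = as.character(modCode))
}

#' Parse a scheme spec string of the form "MOTIF:OFFSET:CODE"
#'
#' The compact command-line format, e.g. \code{"CG:0:M"} for 5mCpG or
#' \code{"GC:1:M"} for 5mGpC.
#'
#' @param spec Character scalar \code{"MOTIF:OFFSET:CODE"}.
#' @return A \linkS4class{ModificationScheme}.
#' @examples
#' parseScheme("GC:1:M")
#' @export
parseScheme <- function(spec) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
        stop("scheme spec must be 'MOTIF:OFFSET:CODE', got '", spec, "'")
    ModificationScheme(parts[1L], as.integer(parts[2L]), parts[3L])
}

#' @describeIn ModificationScheme-accessors The motif string.
#' @export
motif <- function(scheme) scheme@motif

#' Accessors for ModificationScheme
#'
#' @param scheme A \linkS4class{ModificationScheme}.
#' @name ModificationScheme-accessors
#' @return \code{motif}: the motif string; \code{modOffset}: 0-based offset
#'   of the modified base; \code{modCode}: the modification code;
#'   \code{canonicalBase}: the canonical identity of the modified base.
NULL

#' @describeIn ModificationScheme-accessors 0-based modified-base offset.
#' @export
modOffset <- function(scheme) scheme@modOffset

#' @describeIn ModificationScheme-accessors The modification code character.
#' @export
modCode <- function(scheme) scheme@modCode

#' @describeIn ModificationScheme-accessors Canonical base at the modified
#'   position.
#' @export
canonicalBase <- function(scheme)
    substr(scheme@motif, scheme@modOffset + 1L, scheme@modOffset + 1L)

#' Motif footprint of a modification position
#'
#' The k-mer positions occupied by the motif when the modified base sits at
#' 1-based position \code{m}. For CpG (\code{"CG"}, offset 0) and m = 4 in a
#' 6-mer this is positions 4 and 5. Pattern rules are never placed on the
#' footprint: the partner bases there are fixed by the motif.
#'
#' @param scheme A \linkS4class{ModificationScheme}.
#' @param m 1-based modification position(s).
#' @return A list (one element per \code{m}) of integer position vectors.
#' @examples
#' motifFootprint(ModificationScheme("CG", 0, "M"), 4L)
#' @export
motifFootprint <- function(scheme, m) {
    start <- as.integer(m) - scheme@modOffset
    lapply(start, function(s) seq.int(s, s + nchar(scheme@motif) - 1L))
}

#' Valid complete-motif modification positions in a k-mer window
#'
#' 1-based positions where the modified base can sit with its whole motif
#' inside the window.
#' @param scheme A \linkS4class{ModificationScheme}.
#' @param k k-mer length.
#' @return Integer vector of positions.
#' @keywords internal
completeMotifPositions <- function(scheme, k) {
    w <- nchar(scheme@motif)
    if (k < w) stop("k must be at least the motif length")
    seq.int(1L + scheme@modOffset, k - w + 1L + scheme@modOffset)
}

#' Replace modification codes by their canonical base
#'
#' @param kmers Character vector of (possibly) modified k-mers.
#' @param scheme A \linkS4class{ModificationScheme}.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonicalizeKmers("TTAAMG", ModificationScheme("CG", 0, "M"))
#' @export
canonicalizeKmers <- function(kmers, scheme)
    gsub(scheme@modCode, canonicalBase(scheme), kmers, fixed = TRUE)

setMethod("show", "ModificationScheme", function(object) {
    motif_marked <- paste0(
        substr(object@motif, 1L, object@modOffset),
        "[", substr(object@motif, object@modOffset + 1L,
                    object@modOffset + 1L), "->", object@modCode, "]",
        substr(object@motif, object@modOffset + 2L, nchar(object@motif)))
    cat("ModificationScheme: motif ", object@motif, ", modified base ",
        motif_marked, "\n", sep = "")
})
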