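#' Create a KmerModel from an entries table
#'
#' @param entries A \code{data.frame} with columns \code{kmer},
#'   \code{level_mean}, \code{level_stdv} (plus optional \code{sd_mean},
#'   \code{sd_stdv} and extra columns).
#' @param alphabet Character vector of allowed characters; inferred from the
#'   k-mers when \code{NULL} (ACGT first, then any modification codes).
#' @param header Verbatim header lines; a minimal default is constructed
#'   when omitted.
#' @return A \linkS4class{KmerModel}.
#' @examples
#' KmerModel(data.frame(kmer = c("AA", "AC"),
#'                      level_mean = c(80, 81.5), level_stdv = 2))
#' @export
KmerModel <- function(entries, alphabet = NULL, header = NULL) {
    entries <- as.data.frame(entries)
    entries$kmer <- as.character(entries$kmer)
    k <- if (nrow(entries)) nchar(entries$kmer[1L]) else 0L
    if (is.null(alphabet)) {
        used <- unique(strsplit(paste(entries$kmer, collapse = ""), "")[[1L]])
        alphabet <- c(CANONICAL_BASES, sort(setdiff(used, CANONICAL_BASES)))
    }
    if (is.null(header))
        header <- c("#model: poreImpute",
                    paste(names(entries), collapse = "\t"))
    new("KmerModel", k = as.integer(k), alphabet = alphabet,
        entries = entries, header = header)
}

#' Accessors for KmerModel
#'
#' @param model A \linkS4class{KmerModel}.
#' @param kmers Character vector of k-mers to look up.
#' @name KmerModel-accessors
#' @return \code{kmerSize}: the k-mer length; \code{modelAlphabet}: the
#'   alphabet; \code{modelEntries}: the entries \code{data.frame};
#'   \code{modelHeader}: verbatim header lines; \code{modelKmers}: the k-mer
#'   strings; \code{levelMeans}: named numeric vector of expected levels
#'   (all entries, or the requested k-mers).
NULL

#' @describeIn KmerModel-accessors k-mer length.
#' @export
kmerSize <- function(model) model@k

#' @describeIn KmerModel-accessors Model alphabet.
#' @export
modelAlphabet <- function(model) model@alphabet

#' @describeIn KmerModel-accessors Entries table.
#' @export
modelEntries <- function(model) model@entries

#' @describeIn KmerModel-accessors Verbatim header lines.
#' @export
modelHeader <- function(model) model@header

#' @describeIn KmerModel-accessors k-mer strings.
#' @export
modelKmers <- function(model) model@entries$kmer

#' @describeIn KmerModel-accessors Expected current levels, named by k-mer.
#' @export
levelMeans <- function(model, kmers = NULL) {
    lv <- stats::setNames(model@entries$level_mean, model@entries$kmer)
    if (is.null(kmers)) lv else {
        hit <- match(kmers, model@entries$kmer)
        if (anyNA(hit))
            stop("k-mer(s) absent from model: ",
                 paste(head(kmers[is.na(hit)], 5L), collapse = ", "))
        stats::setNames(model@entries$level_mean[hit], kmers)
    }
}

#' Modified k-mers of a model
#'
#' K-mers containing at least one character outside ACGT.
#' @param model A \linkS4class{KmerModel}.
#' @return Character vector.
#' @export
modifiedKmers <- function(model) {
    km <- model@entries$kmer
    km[grepl(paste0("[^", paste(CANONICAL_BASES, collapse = ""), "]"), km)]
}

setMethod("show", "KmerModel", function(object) {
    cat("KmerModel: k = ", object@k, ", alphabet {",
        paste(object@alphabet, collapse = ""), "}, ",
        nrow(object@entries), " entries\n", sep = "")
    nmod <- length(modifiedKmers(object))
    if (nmod) cat("  of which modified: ", nmod, "\n", sep = "")
    if (nrow(object@entries))
        cat("  level_mean range: [",
            sprintf("%.3f", min(object@entries$level_mean)), ", ",
            sprintf("%.3f", max(object@entries$level_mean)), "]\n", sep = "")
})

# all 4^k canonical k-mers in lexicographic (byte) order
allCanonicalKmers <- function(k) {
    grids <- rev(rep(list(CANONICAL_BASES), k))
    g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
    sort(do.call(paste0, rev(g)), method = "radix")
}
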