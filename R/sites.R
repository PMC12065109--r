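#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAString
#'   DNAStringSet reverseComplement vmatchPattern
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

# accept a DNAStringSet or a FASTA path; sequences uppercased
asGenome <- function(genome) {
    if (is.character(genome) && length(genome) == 1L && file.exists(genome))
        genome <- readDNAStringSet(genome)
    if (is.character(genome))
        genome <- DNAStringSet(toupper(genome))
    if (!methods::is(genome, "DNAStringSet"))
        stop("genome must be a DNAStringSet, a FASTA path, or sequences")
    if (!length(genome)) return(genome)
    if (is.null(names(genome)))
        names(genome) <- paste0("contig", seq_along(genome))
    # keep only the first whitespace-delimited token of FASTA headers
    names(genome) <- sub("\\s.*$", "", names(genome))
    genome
}

#' Scan a genome for modification motif sites
#'
#' Finds all occurrences of the scheme's motif and reports the position of
#' the base that would be modified. Minus-strand sites (occurrences of the
#' reverse-complemented motif) are reported with the modified base's
#' forward-strand coordinate. Motif occurrences overlapping an N are
#' skipped.
#'
#' @param genome A \code{DNAStringSet}, plain character sequences, or a
#'   FASTA file path.
#' @param scheme A \linkS4class{ModificationScheme}.
#' @param bothStrands Scan the minus strand too (default TRUE: enzymatic
#'   modification acts on both strands).
#' @return A \code{GRanges} of width-1 ranges at the modified base (1-based,
#'   forward coordinates) with strand.
#' @examples
#' scanMotifs(c(chr1 = "ACGT"), ModificationScheme("CG", 0, "M"))
#' @export
scanMotifs <- function(genome, scheme, bothStrands = TRUE) {
    genome <- asGenome(genome)
    w <- nchar(scheme@motif)
    grab <- function(pattern, offset, strand) {
        if (!length(genome))
            return(data.frame(contig = character(0), pos = integer(0),
                              strand = character(0)))
        hits <- vmatchPattern(pattern, genome, fixed = TRUE)
        starts <- IRanges::start(hits)
        n <- vapply(starts, length, integer(1L))
        contig <- rep(names(genome), n)
        data.frame(contig = contig,
                   pos = as.integer(unlist(starts, use.names = FALSE)) +
                         offset,
                   strand = rep(strand, length(contig)))
    }
    df <- grab(scheme@motif, scheme@modOffset, "+")
    if (bothStrands) {
        rc <- as.character(reverseComplement(DNAString(scheme@motif)))
        df <- rbind(df, grab(rc, w - 1L - scheme@modOffset, "-"))
    }
    if (!length(genome)) return(GRanges())
    gr <- GRanges(df$contig, IRanges(df$pos, width = 1L),
                  strand = df$strand,
                  seqlengths = stats::setNames(Biostrings::width(genome),
                                               names(genome)))
    sort(gr, ignore.strand = TRUE)
}

#' Modified k-mers overlapping motif sites
#'
#' For each site, the k - |motif| + 1 k-mers whose window fully contains
#' the motif, with the modification code substituted at the modified base
#' (e.g. context TTAACGAATT with k = 6 and a CpG scheme yields TTAAMG
#' through MGAATT). Windows running off a contig end are dropped, so sites
#' near contig edges yield fewer k-mers.
#'
#' @param genome A \code{DNAStringSet}, sequences, or FASTA path.
#' @param sites A \code{GRanges} as returned by \code{\link{scanMotifs}}.
#' @param k k-mer length.
#' @param scheme A \linkS4class{ModificationScheme}.
#' @return A list of character vectors, one per site.
#' @export
siteKmers <- function(genome, sites, k, scheme) {
    genome <- asGenome(genome)
    k <- as.integer(k)
    w <- nchar(scheme@motif)
    seqs <- stats::setNames(as.character(genome), names(genome))
    n <- length(sites)
    if (!n) return(list())
    sn <- as.character(GenomicRanges::seqnames(sites))
    if (!all(sn %in% names(seqs)))
        stop("unknown contig: ", setdiff(sn, names(seqs))[1L])
    pos <- GenomicRanges::start(sites)
    std <- as.character(GenomicRanges::strand(sites))
    contig <- seqs[sn]
    L <- nchar(contig)
    # motif forward interval [a, b] for each site
    a <- ifelse(std == "+", pos - scheme@modOffset,
                pos + scheme@modOffset - w + 1L)
    b <- a + w - 1L
    lo <- pmax(1L, b - k + 1L)
    hi <- pmin(a, L - k + 1L)
    cnt <- pmax(0L, hi - lo + 1L)
    idx <- rep.int(seq_len(n), cnt)
    starts <- sequence(cnt, from = lo)
    kmers <- substring(contig[idx], starts, starts + k - 1L)
    minus <- std[idx] == "-"
    if (any(minus))
        kmers[minus] <- as.character(
            reverseComplement(DNAStringSet(kmers[minus])))
    at <- ifelse(minus, starts + k - pos[idx], pos[idx] - starts + 1L)
    kmers <- paste0(substr(kmers, 1L, at - 1L), scheme@modCode,
                    substr(kmers, at + 1L, k))
    ok <- grepl(paste0("^[", paste(CANONICAL_BASES, collapse = ""),
                       scheme@modCode, "]+$"), kmers)
    unname(split(kmers[ok], factor(idx[ok], levels = seq_len(n))))
}

#' Fraction of all complete-motif modified k-mers a genome covers
#'
#' The union of \code{\link{siteKmers}} over all motif sites, divided by
#' the number of possible complete-motif single-modification k-mers.
#'
#' @inheritParams siteKmers
#' @param bothStrands Scan both strands (default TRUE).
#' @return Fraction in [0, 1].
#' @export
motifCoverage <- function(genome, scheme, k, bothStrands = TRUE) {
    genome <- asGenome(genome)
    sites <- scanMotifs(genome, scheme, bothStrands)
    got <- unique(unlist(siteKmers(genome, sites, k, scheme)))
    length(got) / length(enumerateModifiedKmers(k, scheme, FALSE))
}

#' Select a near-minimal training site set reaching a coverage target
#'
#' Visits the genome's motif sites in a seeded uniform-random order,
#' accepting a site only if it contributes at least one modified k-mer not
#' yet covered, and stops at the first acceptance where the covered
#' fraction of all possible complete-motif k-mers reaches
#' \code{targetFraction}. Deterministic given the seed.
#'
#' @inheritParams motifCoverage
#' @param targetFraction Target fraction T in (0, 1] of unique modified
#'   k-mers to cover.
#' @param seed Integer seed for the site ordering.
#' @return A \linkS4class{SiteSelection}.
#' @export
selectTrainingSites <- function(genome, scheme, k, targetFraction,
                                seed = 1L, bothStrands = TRUE) {
    stopifnot(targetFraction > 0, targetFraction <= 1)
    genome <- asGenome(genome)
    k <- as.integer(k)
    sites <- scanMotifs(genome, scheme, bothStrands)
    kml <- siteKmers(genome, sites, k, scheme)
    universe <- enumerateModifiedKmers(k, scheme, FALSE)
    n_total <- length(universe)
    covered <- logical(n_total)
    set.seed(as.integer(seed))
    ord <- sample.int(length(sites))
    accepted <- integer(0)
    reached <- FALSE
    for (i in ord) {
        idx <- match(kml[[i]], universe)
        idx <- idx[!is.na(idx)]
        if (!any(!covered[idx])) next
        covered[idx] <- TRUE
        accepted <- c(accepted, i)
        if (sum(covered) / n_total >= targetFraction) {
            reached <- TRUE
            break
        }
    }
    if (!reached)
        stop(sprintf(paste0("coverage shortfall: genome reaches at most ",
                            "%.4f of modified k-mers, below target %.4f"),
                     sum(covered) / n_total, targetFraction))
    new("SiteSelection", sites = sites[accepted],
        coveredKmers = universe[covered],
        targetFraction = as.numeric(targetFraction),
        achievedFraction = sum(covered) / n_total,
        seed = as.integer(seed), scheme = scheme, k = k)
}

#' @describeIn SiteSelection Accepted sites (\code{GRanges}, acceptance
#'   order).
#' @param selection A \linkS4class{SiteSelection}.
#' @export
selectedSites <- function(selection) selection@sites

#' @describeIn SiteSelection Covered modified k-mers.
#' @export
coveredKmers <- function(selection) selection@coveredKmers

#' @describeIn SiteSelection Achieved coverage fraction.
#' @export
achievedFraction <- function(selection) selection@achievedFraction

setMethod("show", "SiteSelection", function(object) {
    cat("SiteSelection: ", length(object@sites), " sites covering ",
        length(object@coveredKmers), " modified ", object@k, "-mers (",
        sprintf("%.1f%%", 100 * object@achievedFraction), ", target ",
        sprintf("%.1f%%", 100 * object@targetFraction), ", seed ",
        object@seed, ")\n", sep = "")
})

#' Write motif sites as BED
#'
#' BED uses 0-based half-open coordinates; the width-1 intervals mark the
#' modified base.
#'
#' @param sites A \code{GRanges} or \linkS4class{SiteSelection}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSitesBed <- function(sites, path) {
    if (methods::is(sites, "SiteSelection")) sites <- sites@sites
    rtracklayer::export(sites, path, format = "BED")
    invisible(path)
}
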