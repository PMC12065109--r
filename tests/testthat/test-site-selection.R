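# naive substring-scan oracle for motif occurrences (forward strand):
# returns 1-based positions of the modified base
naiveScan <- function(seq, pattern, offset) {
    hits <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else as.integer(hits) + offset
}

test_that("motif scanning finds forward and reverse sites", {
    gr <- scanMotifs(c(chr1 = "ACGT"), cpgScheme(), bothStrands = FALSE)
    expect_length(gr, 1L)
    expect_identical(GenomicRanges::start(gr), 2L)  # 0-based position 1
    expect_identical(as.character(GenomicRanges::strand(gr)), "+")
    # CG is its own reverse complement: a second, minus-strand site appears
    gr2 <- scanMotifs(c(chr1 = "ACGT"), cpgScheme(), bothStrands = TRUE)
    expect_length(gr2, 2L)
    expect_setequal(GenomicRanges::start(gr2), c(2L, 3L))
    expect_length(scanMotifs(Biostrings::DNAStringSet(), cpgScheme()), 0L)
})

test_that("sites overlapping N and non-palindromic motifs behave", {
    gr <- scanMotifs(c(c1 = "ACNGTGCA"), gpcScheme(), bothStrands = TRUE)
    # forward GC at 6-7 (mod base position 7); reverse complement of GC is
    # GC itself at motif level
    expect_true(all(GenomicRanges::start(gr) %in% c(6L, 7L)))
    # N never matches
    expect_length(scanMotifs(c(c1 = "ANGNCN"), cpgScheme()), 0L)
})

test_that("scan counts match a brute-force substring scan on 10 kb", {
    g <- simulateGenome(10000, seed = 33L)
    seq <- as.character(g[[1L]])
    fwd <- naiveScan(seq, "CG", 0L)
    gr <- scanMotifs(g, cpgScheme(), bothStrands = FALSE)
    expect_identical(GenomicRanges::start(gr), fwd)
    # both strands: CG reverse sites sit one base right of the forward C
    gr2 <- scanMotifs(g, cpgScheme(), bothStrands = TRUE)
    expect_length(gr2, 2L * length(fwd))
})

test_that("site k-mers walk the motif across the window", {
    g <- c(ctx = "TTAACGAATT")
    sites <- scanMotifs(g, cpgScheme(), bothStrands = FALSE)
    km <- siteKmers(g, sites, 6L, cpgScheme())[[1L]]
    expect_length(km, 5L)
    expect_identical(km[1L], "TTAAMG")
    expect_identical(km[5L], "MGAATT")
    # minus-strand k-mers read on the reverse complement
    sites2 <- scanMotifs(g, cpgScheme(), bothStrands = TRUE)
    minus <- sites2[GenomicRanges::strand(sites2) == "-"]
    km2 <- siteKmers(g, minus, 6L, cpgScheme())[[1L]]
    expect_length(km2, 5L)
    expect_identical(km2[1L], "MGTTAA")  # rc of TTAACG, M at the minus C
    expect_identical(km2[5L], "AATTMG")  # rc of CGAATT
})

test_that("contig ends truncate the k-mer windows", {
    g <- c(edge = "CGAATTA")
    sites <- scanMotifs(g, cpgScheme(), bothStrands = FALSE)
    km <- siteKmers(g, sites, 6L, cpgScheme())[[1L]]
    expect_identical(km, "MGAATT")
})

test_that("site k-mers agree with brute-force window enumeration", {
    g <- simulateGenome(500, seed = 44L)
    seq <- as.character(g[[1L]])
    sites <- scanMotifs(g, cpgScheme(), bothStrands = FALSE)
    got <- siteKmers(g, sites, 6L, cpgScheme())
    for (i in seq_along(sites)) {
        p <- GenomicRanges::start(sites)[i]
        expected <- character(0)
        for (w0 in (p - 4L):p) {      # windows containing the CG at [p, p+1]
            if (w0 < 1L || w0 + 5L > nchar(seq)) next
            kmer <- substring(seq, w0, w0 + 5L)
            substr(kmer, p - w0 + 1L, p - w0 + 1L) <- "M"
            expected <- c(expected, kmer)
        }
        expect_identical(got[[i]], expected)
    }
})

test_that("coverage is a fraction of the complete-motif inventory", {
    expect_identical(motifCoverage(c(x = "AAAA"), cpgScheme(), 2L), 0)
    expect_equal(motifCoverage(c(x = "ACGT"), cpgScheme(), 2L), 1)
    g1 <- simulateGenome(2000, seed = 3L)
    g2 <- simulateGenome(2000, seed = 4L)
    both <- Biostrings::DNAStringSet(c(a = as.character(g1[[1L]]),
                                       b = as.character(g2[[1L]])))
    # monotone non-decreasing under concatenation
    expect_gte(motifCoverage(both, cpgScheme(), 6L),
               motifCoverage(g1, cpgScheme(), 6L))
})

test_that("training-site selection is greedy, seeded and deterministic", {
    g <- simulateGenome(5000, seed = 55L)
    s1 <- selectTrainingSites(g, cpgScheme(), 6L, 0.25, seed = 9L)
    s2 <- selectTrainingSites(g, cpgScheme(), 6L, 0.25, seed = 9L)
    expect_identical(coveredKmers(s1), coveredKmers(s2))
    expect_identical(GenomicRanges::start(selectedSites(s1)),
                     GenomicRanges::start(selectedSites(s2)))
    expect_gte(achievedFraction(s1), 0.25)
    # dropping the last accepted site falls below the target
    km <- siteKmers(g, selectedSites(s1), 6L, cpgScheme())
    n_without_last <- length(unique(unlist(km[-length(km)])))
    expect_lt(n_without_last / 1280, 0.25)
    # replay: every accepted site contributed at least one new k-mer
    seen <- character(0)
    for (x in km) {
        expect_gt(length(setdiff(x, seen)), 0L)
        seen <- union(seen, x)
    }
    expect_setequal(seen, coveredKmers(s1))
})

test_that("selection exhausts the genome at the full coverage target", {
    g <- simulateGenome(3000, seed = 66L)
    cov <- motifCoverage(g, cpgScheme(), 6L)
    sel <- selectTrainingSites(g, cpgScheme(), 6L, cov, seed = 2L)
    sites <- scanMotifs(g, cpgScheme())
    inventory <- unique(unlist(siteKmers(g, sites, 6L, cpgScheme())))
    inventory <- intersect(inventory, enumerateModifiedKmers(6L, cpgScheme()))
    expect_setequal(coveredKmers(sel), inventory)
    # an unreachable target reports the shortfall
    expect_error(selectTrainingSites(g, cpgScheme(), 6L,
                                     min(1, cov + 0.01), seed = 2L),
                 "coverage shortfall")
})

test_that("BED export writes 0-based width-1 intervals", {
    g <- c(chr1 = "ACGT")
    sel_gr <- scanMotifs(g, cpgScheme(), bothStrands = FALSE)
    path <- tempfile(fileext = ".bed")
    writeSitesBed(sel_gr, path)
    fields <- strsplit(readLines(path)[1L], "\t")[[1L]]
    expect_identical(fields[1L], "chr1")
    expect_identical(fields[2L], "1")   # 0-based start of the C
    expect_identical(fields[3L], "2")
})
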