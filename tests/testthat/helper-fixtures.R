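# shared fixtures: schemes, toy models and the 3-mer walkthrough objects

cpgScheme <- function() ModificationScheme("CG", 0L, "M")
gpcScheme <- function() ModificationScheme("GC", 1L, "M")
# single-base motif: any C can be modified (3-mer toy examples)
cScheme <- function() ModificationScheme("C", 0L, "M")

# complete canonical 3-mer model with ACT pinned to 11
toyCanonical <- function(seed = 11L) {
    m <- simulateCanonicalModel(3L, seed = seed)
    e <- modelEntries(m)
    e$level_mean[e$kmer == "ACT"] <- 11
    KmerModel(e, header = modelHeader(m))
}

# the toy rule set: center-position rule -4, A at 1 -> -2, T at 3 -> +1
toyRules <- function() {
    RuleSet(data.frame(
        order = 1:3, mod_position = 2L,
        kind = c("position", "pattern", "pattern"),
        pattern_position = c(NA, 1L, 3L),
        pattern_base = c(NA, "A", "T"),
        shift = c(-4, -2, 1)), cScheme(), 3L)
}

# delta table whose position median is -4 and whose A-at-1 residuals are
# {-3, -1}, diluted so (f = 1, b = A) is the unique largest candidate
toyDelta <- function() {
    DeltaTable(data.frame(
        kmer = c("AMA", "AMC", "CMC", "GMG", "TMT", "CMA", "GMC"),
        mod_position = 2L,
        delta = c(-7, -5, -4, -4, -4, -4, -4)), cScheme(), 3L)
}

# brute-force enumeration oracle: all strings over ACGT+code with exactly
# one code character whose motif (code substituted at the modified base)
# sits fully inside the window
bruteForceModifiedKmers <- function(k, scheme) {
    ab <- c("A", "C", "G", "T", modCode(scheme))
    g <- do.call(expand.grid, c(rep(list(ab), k), stringsAsFactors = FALSE))
    all_strings <- do.call(paste0, g)
    want <- strsplit(motif(scheme), "")[[1L]]
    want[modOffset(scheme) + 1L] <- modCode(scheme)
    keep <- vapply(all_strings, function(x) {
        chars <- strsplit(x, "")[[1L]]
        at <- which(chars == modCode(scheme))
        if (length(at) != 1L) return(FALSE)
        fp <- seq.int(at - modOffset(scheme),
                      at - modOffset(scheme) + length(want) - 1L)
        if (any(fp < 1L) || any(fp > k)) return(FALSE)
        all(chars[fp] == want)
    }, logical(1L))
    sort(all_strings[keep], method = "radix")
}

# naive per-k-mer delta oracle: sum of all rule shifts applying to x
bruteForceDelta <- function(x, rules) {
    rl <- ruleTable(rules)
    chars <- strsplit(x, "")[[1L]]
    code <- modCode(rules@scheme)
    total <- 0
    for (j in seq_len(nrow(rl))) {
        if (chars[rl$mod_position[j]] != code) next
        if (rl$kind[j] == "pattern" &&
            chars[rl$pattern_position[j]] != rl$pattern_base[j]) next
        total <- total + rl$shift[j]
    }
    total
}

writeTempModel <- function(lines) {
    path <- tempfile(fileext = ".model")
    writeLines(lines, path)
    path
}
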