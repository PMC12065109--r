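#' Read a pore-model table (Nanopolish/f5c dialect)
#'
#' The dialect is: any number of \code{#}-prefixed metadata lines, one
#' optional column-header line, then tab-separated data rows
#' \code{kmer level_mean level_stdv [sd_mean sd_stdv ...]}. Header lines are
#' preserved verbatim so that \code{writePoreModel(readPoreModel(f))}
#' reproduces the values of \code{f}. Extra columns are carried along but
#' ignored by all computations.
#'
#' @param path Path to a pore-model TSV file.
#' @return A \linkS4class{KmerModel}.
#' @seealso [writePoreModel()]
#' @export
readPoreModel <- function(path) {
    if (!file.exists(path)) stop("no such model file: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    is_meta <- startsWith(lines, "#")
    n_meta <- if (any(!is_meta)) which(!is_meta)[1L] - 1L else length(lines)
    header <- lines[seq_len(n_meta)]
    body <- lines[seq.int(n_meta + 1L, length.out = length(lines) - n_meta)]
    std_cols <- c("kmer", "level_mean", "level_stdv", "sd_mean", "sd_stdv")
    col_names <- NULL
    if (length(body)) {
        first <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
        # a column-header line has a non-numeric second field
        if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))) {
            header <- c(header, body[1L])
            col_names <- first
            body <- body[-1L]
        }
    }
    if (!length(body))
        return(KmerModel(data.frame(kmer = character(0),
                                    level_mean = numeric(0),
                                    level_stdv = numeric(0)),
                         header = header))
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2L))
        stop("malformed model line (need kmer + >=1 level column): '",
             body[which(nf < 2L)[1L]], "'")
    if (length(unique(nf)) != 1L)
        stop("inconsistent number of columns at line: '",
             body[which(nf != nf[1L])[1L]], "'")
    if (is.null(col_names))
        col_names <- std_cols[seq_len(min(nf[1L], 5L))]
    if (length(col_names) < nf[1L])
        col_names <- c(col_names, paste0("V", seq.int(length(col_names) + 1L,
                                                      nf[1L])))
    # files without a column-header line, or with nonstandard names, still
    # map their leading columns onto the standard dialect
    if (!"level_mean" %in% col_names) {
        n_std <- min(length(col_names), 5L)
        col_names[seq_len(n_std)] <- std_cols[seq_len(n_std)]
    }
    m <- matrix(unlist(fields), ncol = nf[1L], byrow = TRUE)
    entries <- data.frame(kmer = m[, 1L], stringsAsFactors = FALSE)
    for (j in 2:ncol(m)) {
        v <- m[, j]
        num <- suppressWarnings(as.numeric(v))
        if (col_names[j] %in% std_cols && anyNA(num))
            stop("non-numeric value in column '", col_names[j],
                 "' at line: '", body[which(is.na(num))[1L]], "'")
        entries[[col_names[j]]] <- if (anyNA(num)) v else num
    }
    if (!"level_stdv" %in% names(entries))
        entries$level_stdv <- 1.0
    kl <- nchar(entries$kmer)
    if (length(unique(kl)) != 1L)
        stop("inconsistent k-mer length at line: '",
             body[which(kl != kl[1L])[1L]], "'")
    KmerModel(entries, header = header)
}

#' Write a pore-model table (Nanopolish/f5c dialect)
#'
#' Emits the stored header lines verbatim, then the entries sorted
#' lexicographically (byte order) by k-mer with numeric columns formatted to
#' six decimal places, so output is byte-stable.
#'
#' @param model A \linkS4class{KmerModel}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @seealso [readPoreModel()]
#' @export
writePoreModel <- function(model, path) {
    e <- model@entries
    if (nrow(e)) e <- e[order(e$kmer, method = "radix"), , drop = FALSE]
    cols <- lapply(e, function(col)
        if (is.numeric(col)) sprintf("%.6f", col) else as.character(col))
    lines <- c(model@header,
               if (nrow(e)) do.call(paste, c(cols, sep = "\t")))
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(path)
}
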