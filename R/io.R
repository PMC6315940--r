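#' Read a base-pairing probability matrix in any supported dialect
#'
#' Dispatches on `format` to one of the dialect readers:
#' \describe{
#'   \item{`dotplot-ps`}{RNAfold PostScript dot plots (`*_dp.ps`), where
#'     `"i j v ubox"` records store the square root of the pairing
#'     probability; see [readDotplotPS()].}
#'   \item{`tabular`}{whitespace-delimited n-by-n probability matrices with
#'     optional `#` comment lines, the shape consensus folders emit; see
#'     [readTabularBP()].}
#'   \item{`sparse`}{simple 3-column `i j p` text; see [readSparseBP()].}
#' }
#'
#' @param file path or connection
#' @param format one of `"dotplot-ps"`, `"tabular"`, `"sparse"`
#' @return a [BasePairMatrix-class]
#' @export
readBasePairMatrix <- function(file, format = c("sparse", "tabular", "dotplot-ps")) {
    format <- match.arg(format)
    switch(format,
        "dotplot-ps" = readDotplotPS(file),
        "tabular"    = readTabularBP(file),
        "sparse"     = readSparseBP(file))
}

#' Read an RNAfold PostScript dot plot
#'
#' Parses the `ubox` records of an RNAfold dot-plot PostScript file
#' (`*_dp.ps`).  Each line `"i j v ubox"` encodes the pairing probability of
#' positions `i < j` as `v = sqrt(p)`, so probabilities are recovered by
#' squaring.  `lbox` records (the MFE structure overlay) are ignored.  The
#' window length is taken from the `/sequence` block when present, otherwise
#' from the largest index seen.
#'
#' @param file path or connection to the PostScript file
#' @return a [BasePairMatrix-class] with `source = "dotplot-ps"`
#' @export
readDotplotPS <- function(file) {
    lines <- readLines(file, warn = FALSE)
    n <- .psSequenceLength(lines)
    ub <- grep("\\bubox\\s*$", lines, value = TRUE)
    ub <- grep("^\\s*%", ub, value = TRUE, invert = TRUE)
    if (!length(ub)) {
        if (is.null(n))
            stop("no ubox records and no /sequence block: cannot determine length")
        return(BasePairMatrix(data.frame(i = integer(), j = integer(),
                                         p = numeric()),
                              n = n, source = "dotplot-ps"))
    }
    parts <- strsplit(trimws(sub("ubox\\s*$", "", ub)), "\\s+")
    bad <- vapply(parts, function(x) length(x) != 3L, logical(1))
    num <- suppressWarnings(lapply(parts, as.numeric))
    bad <- bad | vapply(num, function(x) anyNA(x), logical(1))
    if (any(bad))
        stop(sprintf("malformed ubox record: '%s'", ub[which(bad)[1L]]))
    rec <- do.call(rbind, num)
    i <- rec[, 1L]; j <- rec[, 2L]; v <- rec[, 3L]
    if (any(i != round(i) | j != round(j)))
        stop(sprintf("malformed ubox record (non-integer position): '%s'",
                     ub[which(i != round(i) | j != round(j))[1L]]))
    if (any(i >= j))
        stop(sprintf("malformed ubox record (i >= j): '%s'", ub[which(i >= j)[1L]]))
    if (any(v > 1 + 1e-9) || any(v < 0))
        stop(sprintf("malformed ubox record (sqrt(p) outside [0,1]): '%s'",
                     ub[which(v > 1 + 1e-9 | v < 0)[1L]]))
    if (is.null(n)) n <- max(j)
    if (max(j) > n)
        stop("ubox index exceeds /sequence length")
    BasePairMatrix(data.frame(i = as.integer(i), j = as.integer(j),
                              p = pmin(v, 1)^2),
                   n = n, source = "dotplot-ps")
}

# Length of the sequence in an RNAfold PS "/sequence { (\ ... ) } def" block:
# concatenate the block, take the (...) string literal, drop line-continuation
# backslashes and whitespace, and count the remaining characters.
.psSequenceLength <- function(lines) {
    start <- grep("^/sequence", lines)
    if (!length(start)) return(NULL)
    stop_ <- grep("\\bdef\\b", lines)
    stop_ <- stop_[stop_ >= start[1L]]
    if (!length(stop_)) return(NULL)
    blk <- paste(lines[start[1L]:stop_[1L]], collapse = "")
    open <- regexpr("(", blk, fixed = TRUE)
    close <- regexpr(")", blk, fixed = TRUE)
    if (open < 0 || close < open) return(NULL)
    seqtxt <- substr(blk, open + 1L, close - 1L)
    seqtxt <- gsub("[\\\\[:space:]]", "", seqtxt)
    if (nchar(seqtxt) > 0L) nchar(seqtxt) else NULL
}

#' Read a whitespace-delimited n-by-n probability matrix
#'
#' Reads the tabular dialect: a square numeric matrix, one row per line,
#' optionally preceded or interleaved with `#` comment lines.  Asymmetric
#' inputs beyond a tolerance of `1e-6` are symmetrized by the elementwise
#' maximum with a warning (upper-triangular-only files are therefore read
#' correctly); diagonal entries are forced to zero.
#'
#' @param file path or connection
#' @return a [BasePairMatrix-class] with `source = "tabular"`
#' @export
readTabularBP <- function(file) {
    lines <- readLines(file, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!length(lines)) stop("empty tabular matrix file")
    rows <- strsplit(trimws(lines), "\\s+")
    len <- lengths(rows)
    if (length(unique(len)) != 1L)
        stop(sprintf("ragged rows: line widths %s", paste(unique(len), collapse = ", ")))
    vals <- suppressWarnings(as.numeric(unlist(rows)))
    if (anyNA(vals)) stop("non-numeric entry in tabular matrix")
    m <- matrix(vals, nrow = length(rows), byrow = TRUE)
    if (nrow(m) != ncol(m))
        stop(sprintf("matrix is %d x %d, not square", nrow(m), ncol(m)))
    if (any(vals < -1e-6) || any(vals > 1 + 1e-6))
        stop("matrix values outside [0, 1] beyond tolerance")
    m[m < 0] <- 0; m[m > 1] <- 1
    diag(m) <- 0
    x <- BasePairMatrix(m)
    methods::initialize(x, source = "tabular")
}

#' Read a sparse 3-column base-pair probability file
#'
#' Reads the simple sparse dialect: one `i j p` triple per line (1-based
#' positions, `i < j`), with optional `# n <length>` and other `#` comment
#' lines.  Without an `# n` pragma the window length is the largest index
#' seen.
#'
#' @param file path or connection
#' @return a [BasePairMatrix-class] with `source = "sparse"`
#' @export
readSparseBP <- function(file) {
    lines <- readLines(file, warn = FALSE)
    nprag <- grep("^#\\s*n\\s+\\d+", lines, value = TRUE)
    n <- if (length(nprag)) as.integer(sub("^#\\s*n\\s+(\\d+).*", "\\1", nprag[1L])) else NULL
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!length(lines)) {
        if (is.null(n)) stop("empty sparse file with no '# n' pragma")
        return(BasePairMatrix(data.frame(i = integer(), j = integer(), p = numeric()),
                              n = n, source = "sparse"))
    }
    parts <- strsplit(trimws(lines), "\\s+")
    if (any(lengths(parts) != 3L))
        stop("each sparse record must have exactly three fields: i j p")
    rec <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 3L, byrow = TRUE))
    if (anyNA(rec)) stop("non-numeric field in sparse record")
    if (is.null(n)) n <- as.integer(max(rec[, 1:2]))
    BasePairMatrix(data.frame(i = as.integer(rec[, 1L]), j = as.integer(rec[, 2L]),
                              p = rec[, 3L]),
                   n = n, source = "sparse")
}

#' Write a BasePairMatrix as sparse 3-column text
#'
#' The inverse of [readSparseBP()]: writes a `# n <length>` pragma followed
#' by one `i j p` triple per stored pair (`i < j`), at full double
#' precision so that write/read round-trips are exact to within 1e-9.
#'
#' @param x a [BasePairMatrix-class]
#' @param file path or connection
#' @return `file`, invisibly
#' @export
writeSparseBP <- function(x, file) {
    stopifnot(methods::is(x, "BasePairMatrix"))
    d <- bpPairs(x)
    con <- file
    lines <- c(sprintf("# n %d", bpLength(x)),
               sprintf("# source %s", bpSource(x)),
               sprintf("%d %d %.17g", d$i, d$j, d$p))
    writeLines(lines, con)
    invisible(file)
}

#' Write a BasePairMatrix as a dense whitespace-delimited matrix
#'
#' The inverse of [readTabularBP()]: a full symmetric n-by-n matrix, one
#' row per line, preceded by a `#` comment with the length.
#'
#' @param x a [BasePairMatrix-class]
#' @param file path or connection
#' @return `file`, invisibly
#' @export
writeTabularBP <- function(x, file) {
    stopifnot(methods::is(x, "BasePairMatrix"))
    m <- as.matrix(x)
    lines <- c(sprintf("# n %d", nrow(m)),
               apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")))
    writeLines(lines, file)
    invisible(file)
}
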