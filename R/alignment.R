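#' AlignmentWindow: a multiple sequence alignment window
#'
#' A light container for the alignment windows on which consensus
#' base-pairing probabilities are computed: a set of equal-length gapped
#' RNA sequences plus the identity of the reference row, whose ungapped
#' coordinates predictions are ultimately reported in.  Sequences are
#' stored uppercase with `T` normalised to `U`; the alphabet is
#' `A C G U N -`.
#'
#' @slot seqs named character vector of gapped sequences, all equal width
#' @slot reference name of the reference row
#' @exportClass AlignmentWindow
setClass("AlignmentWindow",
    representation(seqs = "character", reference = "character"))

setValidity("AlignmentWindow", function(object) {
    msg <- character()
    if (!length(object@seqs))
        msg <- c(msg, "alignment has no rows")
    if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
        msg <- c(msg, "rows must have unique names")
    if (length(unique(nchar(object@seqs))) > 1L)
        msg <- c(msg, "all rows must have equal width")
    if (length(object@reference) != 1L ||
        !object@reference %in% names(object@seqs))
        msg <- c(msg, "reference must name one of the rows")
    if (length(object@seqs) &&
        grepl("[^ACGUN-]", paste(object@seqs, collapse = "")))
        msg <- c(msg, "alphabet restricted to A, C, G, U/T, N, -")
    if (length(msg)) msg else TRUE
})

#' Construct an AlignmentWindow
#'
#' @param seqs named character vector of gapped sequences (case and `T`/`U`
#'   are normalised)
#' @param reference name of the reference row; defaults to the first row
#' @return an [AlignmentWindow-class]
#' @examples
#' aln <- AlignmentWindow(c(human = "ACGU-ACG", mouse = "ACGUUACG"))
#' alignmentWidth(aln)
#' @export
AlignmentWindow <- function(seqs, reference = names(seqs)[1L]) {
    seqs <- toupper(seqs)
    seqs <- gsub("T", "U", seqs, fixed = TRUE)
    seqs <- gsub("\\.", "-", seqs)
    methods::new("AlignmentWindow", seqs = seqs, reference = reference)
}

#' @describeIn AlignmentWindow-class the gapped rows (named character)
#' @param x an `AlignmentWindow`
#' @export
alignmentRows <- function(x) x@seqs

#' @describeIn AlignmentWindow-class number of alignment columns
#' @export
alignmentWidth <- function(x) nchar(x@seqs[[1L]])

#' @describeIn AlignmentWindow-class name of the reference row
#' @export
referenceId <- function(x) x@reference

setMethod("show", "AlignmentWindow", function(object) {
    cat(sprintf("AlignmentWindow: %d rows x %d columns (reference: %s)\n",
                length(object@seqs), alignmentWidth(object), object@reference))
})

#' Read an alignment window from FASTA or Clustal
#'
#' Thin wrapper over the Biostrings readers: aligned (gapped) FASTA via
#' `readBStringSet`, Clustal via `readRNAMultipleAlignment`.
#'
#' @param file path
#' @param format `"fasta"` or `"clustal"`
#' @param reference name of the reference row; defaults to the first
#' @return an [AlignmentWindow-class]
#' @export
readAlignmentWindow <- function(file, format = c("fasta", "clustal"),
                                reference = NULL) {
    format <- match.arg(format)
    seqs <- if (format == "fasta") {
        s <- Biostrings::readBStringSet(file)
        stats::setNames(as.character(s), names(s))
    } else {
        m <- Biostrings::readRNAMultipleAlignment(file, format = "clustal")
        s <- as.character(m)
        if (is.null(names(s))) names(s) <- rownames(m)
        s
    }
    if (is.null(reference)) reference <- names(seqs)[1L]
    AlignmentWindow(seqs, reference = reference)
}

.charMatrix <- function(a) {
    do.call(rbind, strsplit(unname(a@seqs), ""))
}

#' Apply alignment quality filters
#'
#' The quality gate applied to benchmark alignment windows before
#' consensus folding: rows with more than `max_gap_frac` gaps are removed
#' (the reference row is never removed — if it fails the gap threshold the
#' whole window is rejected); the filtered alignment must retain at least
#' `min_rows` rows; and its mean pairwise sequence identity must lie in
#' `[mpi_min, mpi_max)`.
#'
#' @param a an [AlignmentWindow-class]
#' @param max_gap_frac maximum tolerated per-row gap fraction (default 0.75;
#'   rows *strictly above* are dropped)
#' @param min_rows minimum surviving rows (default 3)
#' @param mpi_min,mpi_max admissible mean pairwise identity interval,
#'   closed below and open above (defaults 0.60 and 0.95)
#' @return a list with `status` (`"pass"`/`"reject"`), `alignment` (the
#'   filtered [AlignmentWindow-class], or `NULL` on rejection), `reason`
#'   (`NA`, or one of `"reference_gap_fraction"`, `"min_rows"`,
#'   `"mpi_below_min"`, `"mpi_above_max"`), `mpi` (the measured identity,
#'   `NA` when fewer than two rows survive) and `dropped` (names of
#'   removed rows)
#' @export
filterAlignment <- function(a, max_gap_frac = 0.75, min_rows = 3L,
                            mpi_min = 0.60, mpi_max = 0.95) {
    stopifnot(methods::is(a, "AlignmentWindow"))
    gf <- vapply(strsplit(a@seqs, ""), function(ch) mean(ch == "-"), numeric(1))
    res <- function(status, alignment, reason, mpi, dropped)
        list(status = status, alignment = alignment, reason = reason,
             mpi = mpi, dropped = dropped)
    if (gf[[a@reference]] > max_gap_frac)
        return(res("reject", NULL, "reference_gap_fraction", NA_real_,
                   character()))
    keep <- gf <= max_gap_frac | names(a@seqs) == a@reference
    dropped <- names(a@seqs)[!keep]
    filt <- AlignmentWindow(a@seqs[keep], reference = a@reference)
    if (length(filt@seqs) < min_rows)
        return(res("reject", NULL, "min_rows", NA_real_, dropped))
    mpi <- meanPairwiseIdentity(filt)
    if (mpi < mpi_min)
        return(res("reject", NULL, "mpi_below_min", mpi, dropped))
    if (mpi >= mpi_max)
        return(res("reject", NULL, "mpi_above_max", mpi, dropped))
    res("pass", filt, NA_character_, mpi, dropped)
}

#' Mean pairwise sequence identity
#'
#' Identity of a row pair is the fraction of matching positions among the
#' compared ones: positions where both rows have a gap are skipped, a gap
#' against a base counts as a mismatch (set `exclude_gap_base = TRUE` to
#' drop those positions from the denominator instead), and `N` matches
#' nothing.  The scalar MPI averages this over all row pairs.
#'
#' In per-column mode the same pair statistics are aggregated within each
#' column; columns where the reference row has a gap, and columns with
#' more than `max_col_gap_frac` gaps, are ignored (returned as `NA`), the
#' convention used for per-position identity profiles of windows whose
#' alignments exceed the window size through reference gaps.
#'
#' @param a an [AlignmentWindow-class] with at least two rows
#' @param per_column if `TRUE`, return a per-column profile (length =
#'   alignment width, `NA` at ignored columns) instead of a scalar
#' @param max_col_gap_frac per-column gap-fraction ceiling for the profile
#'   (default 0.25)
#' @param exclude_gap_base drop gap-vs-base positions from the denominator
#'   rather than counting them as mismatches (default `FALSE`)
#' @return scalar MPI, or a numeric profile when `per_column = TRUE`
#' @examples
#' aln <- AlignmentWindow(c(a = "ACGU", b = "ACGA"))
#' meanPairwiseIdentity(aln)  # 0.75
#' @export
meanPairwiseIdentity <- function(a, per_column = FALSE,
                                 max_col_gap_frac = 0.25,
                                 exclude_gap_base = FALSE) {
    stopifnot(methods::is(a, "AlignmentWindow"))
    if (length(a@seqs) < 2L)
        stop("mean pairwise identity needs at least two rows")
    M <- .charMatrix(a)
    nr <- nrow(M)
    pairs <- utils::combn(nr, 2L)
    isgap <- M == "-"
    if (!per_column) {
        vals <- apply(pairs, 2L, function(pr) {
            g1 <- isgap[pr[1L], ]; g2 <- isgap[pr[2L], ]
            use <- !(g1 & g2)
            if (exclude_gap_base) use <- use & !(g1 | g2)
            if (!any(use)) return(NA_real_)
            x <- M[pr[1L], use]; y <- M[pr[2L], use]
            mean(x == y & x != "-" & x != "N")
        })
        return(mean(vals, na.rm = TRUE))
    }
    nc <- ncol(M)
    refgap <- isgap[which(names(a@seqs) == a@reference), ]
    colgap <- colMeans(isgap)
    out <- rep(NA_real_, nc)
    ok <- !refgap & colgap <= max_col_gap_frac
    for (cc in which(ok)) {
        g <- isgap[, cc]; ch <- M[, cc]
        m <- 0L; tot <- 0L
        for (t in seq_len(ncol(pairs))) {
            i <- pairs[1L, t]; j <- pairs[2L, t]
            if (g[i] && g[j]) next
            if (g[i] || g[j]) {
                if (!exclude_gap_base) tot <- tot + 1L
                next
            }
            tot <- tot + 1L
            if (ch[i] == ch[j] && ch[i] != "N") m <- m + 1L
        }
        out[cc] <- if (tot) m / tot else NA_real_
    }
    out
}

#' Map alignment columns to ungapped reference coordinates
#'
#' Converts a column interval `[u, v]` of the alignment into positions in
#' the ungapped reference sequence.  If column `u` is a reference gap the
#' start maps to the next reference base at or after `u`; symmetrically the
#' end maps to the previous reference base at or before `v`.  When no
#' reference base lies inside `[u, v]` both coordinates are returned as
#' `NA` (an empty interval).
#'
#' @param a an [AlignmentWindow-class]
#' @param u,v column interval, `1 <= u <= v <= alignmentWidth(a)`
#' @return integer vector `c(start, end)` in reference coordinates, or
#'   `c(NA, NA)` for an empty interval
#' @export
columnsToReference <- function(a, u, v) {
    stopifnot(methods::is(a, "AlignmentWindow"))
    nc <- alignmentWidth(a)
    if (u < 1L || v > nc || u > v)
        stop(sprintf("need 1 <= u <= v <= %d", nc))
    ref <- strsplit(a@seqs[[a@reference]], "")[[1L]]
    nongap <- ref != "-"
    cum <- cumsum(nongap)
    # next reference base at/after u
    after <- which(nongap & seq_len(nc) >= u)
    before <- which(nongap & seq_len(nc) <= v)
    if (!length(after) || !length(before) || after[1L] > v)
        return(c(start = NA_integer_, end = NA_integer_))
    c(start = cum[after[1L]], end = cum[before[length(before)]])
}
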