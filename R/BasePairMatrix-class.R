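#' BasePairMatrix: symmetric base-pairing probability matrices
#'
#' The central data container of the package: a symmetric, sparse matrix of
#' base-pairing probabilities \eqn{p_{mn}} over the positions of a sequence
#' window or the columns of a multiple sequence alignment.  Probabilities are
#' equilibrium pair probabilities from a Boltzmann ensemble (McCaskill-style
#' partition function for single sequences, consensus-folding posteriors for
#' alignments), so every row sum is at most 1: a base pairs with at most one
#' partner in any one structure.
#'
#' @slot probs symmetric sparse numeric matrix (`dsCMatrix`); absent entries
#'   are zero, the diagonal is zero, all values lie in `[0, 1]`.
#' @slot source provenance tag: one of `"dotplot-ps"`, `"tabular"`,
#'   `"sparse"`, `"toyfold"`, `"synthetic"`, `"unknown"`.
#' @slot labels optional per-position annotation (e.g. alignment column
#'   index or reference-sequence position); either empty or length `n`.
#'
#' @details Coordinates are 1-based and inclusive throughout the public
#'   interface.  Rows whose probability mass exceeds 1 beyond a tolerance of
#'   `1e-6` (as happens with rounded third-party output) are rescaled at
#'   construction with a warning rather than rejected.
#'
#' @seealso [readBasePairMatrix()], [scoreMatrix()], [findBoundaries()]
#' @name BasePairMatrix-class
#' @aliases BasePairMatrix-class
#' @exportClass BasePairMatrix
setClass("BasePairMatrix",
    representation(
        probs  = "dsCMatrix",
        source = "character",
        labels = "character"
    )
)

.BP_SOURCES <- c("dotplot-ps", "tabular", "sparse", "toyfold", "synthetic",
                 "unknown")

setValidity("BasePairMatrix", function(object) {
    p <- object@probs
    msg <- character()
    if (nrow(p) != ncol(p))
        msg <- c(msg, "probability matrix must be square")
    v <- p@x
    if (length(v) && (min(v) < 0 || max(v) > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (nrow(p) && any(Matrix::diag(p) != 0))
        msg <- c(msg, "diagonal entries must be zero")
    rs <- Matrix::rowSums(p)
    if (length(rs) && max(rs) > 1 + 1e-6)
        msg <- c(msg, "row probability mass exceeds 1 beyond tolerance")
    if (length(object@source) != 1L || !object@source %in% .BP_SOURCES)
        msg <- c(msg, sprintf("source must be one of: %s",
                              paste(.BP_SOURCES, collapse = ", ")))
    if (length(object@labels) && length(object@labels) != nrow(p))
        msg <- c(msg, "labels must be empty or one per position")
    if (length(msg)) msg else TRUE
})

#' Construct a BasePairMatrix
#'
#' @param x either a square numeric matrix (dense or sparse) of pairing
#'   probabilities, or a data frame of `(i, j, p)` triplets (1-based
#'   positions).
#' @param n window length; required for triplet input, ignored (taken from
#'   `dim`) for matrix input.
#' @param source provenance tag, see [BasePairMatrix-class].
#' @param labels optional per-position labels.
#' @param symmetrize how to reconcile an asymmetric matrix input: `"max"`
#'   takes the elementwise maximum of the two triangles (with a warning when
#'   they disagree beyond `1e-6`), `"error"` rejects.
#'
#' @return a [BasePairMatrix-class] object.  Rows with probability mass
#'   above `1 + 1e-6` are rescaled with a warning.
#'
#' @examples
#' bp <- BasePairMatrix(data.frame(i = 3, j = 10, p = 0.9), n = 12)
#' bpLength(bp)
#' @export
BasePairMatrix <- function(x, n = NULL, source = "unknown", labels = character(),
                           symmetrize = c("max", "error")) {
    symmetrize <- match.arg(symmetrize)
    if (is.data.frame(x)) {
        if (ncol(x) != 3L)
            stop("triplet input must have exactly three columns (i, j, p)")
        if (is.null(n))
            stop("'n' is required for triplet input")
        i <- as.integer(x[[1L]]); j <- as.integer(x[[2L]]); p <- as.numeric(x[[3L]])
        if (length(i) && (any(i < 1L) || any(j < 1L) || any(i > n) || any(j > n)))
            stop("pair positions outside [1, n]")
        if (any(i == j))
            stop("self-pairings (i == j) are not allowed")
        if (anyDuplicated(paste(pmin(i, j), pmax(i, j))))
            stop("duplicate (i, j) pairs in triplet input")
        m <- Matrix::sparseMatrix(i = pmin(i, j), j = pmax(i, j), x = p,
                                  dims = c(n, n))
        m <- Matrix::forceSymmetric(m, uplo = "U")
    } else {
        m <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
        if (nrow(m) != ncol(m))
            stop("probability matrix must be square")
        up <- Matrix::triu(m, k = 1L)
        lo <- Matrix::t(Matrix::tril(m, k = -1L))
        if (max(abs(up - lo)) > 1e-6) {
            if (symmetrize == "error")
                stop("matrix is asymmetric beyond tolerance 1e-6")
            warning("asymmetric input; symmetrized by elementwise maximum")
        }
        sym <- (up + lo + abs(up - lo)) / 2  # elementwise max of triangles
        m <- Matrix::forceSymmetric(sym, uplo = "U")
    }
    m <- Matrix::drop0(m)
    if (length(m@x) && (min(m@x) < -1e-9 || max(m@x) > 1 + 1e-6))
        stop("probabilities must lie in [0, 1]")
    if (length(m@x)) m@x <- pmin(pmax(m@x, 0), 1)
    m <- .rescaleRowMass(m)
    methods::new("BasePairMatrix", probs = methods::as(m, "dsCMatrix"),
                 source = source, labels = as.character(labels))
}

# Rescale rows whose pairing mass exceeds 1 + 1e-6 while preserving symmetry:
# entry (m, n) is scaled by min(f_m, f_n) where f_m = 1/rowsum for offending
# rows and 1 otherwise, so every rescaled row sum is bounded by 1.
.rescaleRowMass <- function(m) {
    rs <- Matrix::rowSums(m)
    bad <- rs > 1 + 1e-6
    if (!any(bad)) return(m)
    warning(sprintf("%d row(s) with pairing mass > 1 were rescaled", sum(bad)))
    f <- ifelse(bad, 1 / rs, 1)
    t <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
    t@x <- t@x * pmin(f[t@i + 1L], f[t@j + 1L])
    Matrix::forceSymmetric(methods::as(t, "CsparseMatrix"), uplo = "U")
}

#' @describeIn BasePairMatrix-class window length (number of positions)
#' @param x a `BasePairMatrix`
#' @export
bpLength <- function(x) nrow(x@probs)

#' @describeIn BasePairMatrix-class the symmetric probability matrix
#'   (sparse `Matrix`)
#' @export
bpProbs <- function(x) x@probs

#' @describeIn BasePairMatrix-class provenance tag
#' @export
bpSource <- function(x) x@source

#' @describeIn BasePairMatrix-class per-position labels (may be empty)
#' @export
bpLabels <- function(x) x@labels

#' @describeIn BasePairMatrix-class pairs above a probability cutoff as a
#'   data frame of `(i, j, p)` with `i < j`
#' @param cutoff minimum probability to report
#' @export
bpPairs <- function(x, cutoff = 0) {
    t <- methods::as(methods::as(x@probs, "generalMatrix"), "TsparseMatrix")
    keep <- t@i < t@j & t@x > cutoff
    d <- data.frame(i = t@i[keep] + 1L, j = t@j[keep] + 1L, p = t@x[keep])
    d[order(d$i, d$j), , drop = FALSE]
}

#' @export
setMethod("dim", "BasePairMatrix", function(x) dim(x@probs))

#' @export
setMethod("show", "BasePairMatrix", function(object) {
    np <- sum(object@probs@x > 0)
    cat(sprintf("BasePairMatrix of %d positions (%s)\n",
                bpLength(object), object@source))
    cat(sprintf("  %d stored pair probabilities", np))
    if (np)
        cat(sprintf(", max %.4g", max(object@probs@x)))
    cat("\n")
})

#' Dense matrix view of a BasePairMatrix
#' @param x a [BasePairMatrix-class]
#' @param ... ignored
#' @return a base dense numeric matrix
#' @export
setMethod("as.matrix", "BasePairMatrix", function(x, ...) {
    as.matrix(x@probs)
})
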