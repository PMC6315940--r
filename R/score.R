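#' Fitness-function parameters
#'
#' `ScoreParams` holds the two tunable parameters of the segment fitness:
#' the null-model pairing probability `p0` against which log-odds base-pair
#' scores are computed (pairs at or below `p0` score zero), and the flanking
#' margin length `f` in nucleotides over which spanning base pairs are
#' penalised.  Defaults are `p0 = 0.0005` and `f = 10`, the benchmark
#' settings.
#'
#' @slot p0 null-model pairing probability, in (0, 1)
#' @slot f flanking margin length in nt, non-negative integer
#' @exportClass ScoreParams
setClass("ScoreParams", representation(p0 = "numeric", f = "integer"))

setValidity("ScoreParams", function(object) {
    msg <- character()
    if (length(object@p0) != 1L || !is.finite(object@p0) ||
        object@p0 <= 0 || object@p0 >= 1)
        msg <- c(msg, "p0 must be a single number in (0, 1)")
    if (length(object@f) != 1L || is.na(object@f) || object@f < 0L)
        msg <- c(msg, "f must be a single non-negative integer")
    if (length(msg)) msg else TRUE
})

#' @param p0 null-model pairing probability (default 0.0005)
#' @param f flanking margin length in nt (default 10)
#' @return a `ScoreParams` object
#' @rdname ScoreParams-class
#' @examples
#' ScoreParams()
#' ScoreParams(p0 = 0.01, f = 20)
#' @export
ScoreParams <- function(p0 = 0.0005, f = 10L) {
    methods::new("ScoreParams", p0 = as.numeric(p0), f = as.integer(f))
}

#' @describeIn ScoreParams-class the null-model probability
#' @param x a `ScoreParams`
#' @export
nullProb <- function(x) x@p0

#' @describeIn ScoreParams-class the flanking margin length
#' @export
flankLength <- function(x) x@f

setMethod("show", "ScoreParams", function(object) {
    cat(sprintf("ScoreParams: p0 = %g, f = %d\n", object@p0, object@f))
})

#' Comparator fitness weights
#'
#' Weights of the comparator segment fitness of Dotu and colleagues:
#' `w1` multiplies base-pairing probability mass inside the candidate
#' segment, `w2` the mass crossing its boundaries.  The recommended
#' combination, tuned on microRNA (single-hairpin) structures, is
#' `w1 = 2`, `w2 = 1`.
#'
#' @slot w1 inside-pair weight (non-negative)
#' @slot w2 crossing-pair weight (non-negative)
#' @exportClass DotuParams
setClass("DotuParams", representation(w1 = "numeric", w2 = "numeric"))

setValidity("DotuParams", function(object) {
    if (length(object@w1) != 1L || length(object@w2) != 1L ||
        !is.finite(object@w1) || !is.finite(object@w2) ||
        object@w1 < 0 || object@w2 < 0)
        "weights w1, w2 must be single non-negative numbers"
    else TRUE
})

#' @param w1 inside-pair weight (default 2)
#' @param w2 crossing-pair weight (default 1)
#' @return a `DotuParams` object
#' @rdname DotuParams-class
#' @export
DotuParams <- function(w1 = 2, w2 = 1) {
    methods::new("DotuParams", w1 = as.numeric(w1), w2 = as.numeric(w2))
}

#' @describeIn DotuParams-class the weights as a named vector
#' @param x a `DotuParams`
#' @export
dotuWeights <- function(x) c(w1 = x@w1, w2 = x@w2)

setMethod("show", "DotuParams", function(object) {
    cat(sprintf("DotuParams: w1 = %g, w2 = %g\n", object@w1, object@w2))
})

#' Log-odds base-pair score
#'
#' Transforms a base-pairing probability into a score in `[0, 1]` against a
#' null model of random pairing:
#' \deqn{s(p) = \max\left(0, \frac{\log(p/p_0)}{\log(1/p_0)}\right)}
#' The score is 0 for probabilities at or below the null probability `p0`
#' and reaches 1 at `p = 1`; the normalisation by `log(1/p0)` keeps the
#' transform independent of the logarithm base.  Replacing probabilities
#' with these scores prevents boundary estimates from being dominated by a
#' handful of near-certain pairs.
#'
#' @param p numeric vector of probabilities in `[0, 1]`
#' @param params a [ScoreParams()] object (only `p0` is used)
#' @return numeric vector of scores in `[0, 1]`
#' @examples
#' bpScore(c(0, 0.0005, 1), ScoreParams())
#' bpScore(sqrt(0.0005), ScoreParams())  # exactly 0.5
#' @export
bpScore <- function(p, params = ScoreParams()) {
    stopifnot(methods::is(params, "ScoreParams"))
    methods::validObject(params)
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("probabilities must lie in [0, 1]")
    s <- suppressWarnings(log(p / params@p0) / log(1 / params@p0))
    pmax(0, s)
}

#' Apply the base-pair score transform to a whole matrix
#'
#' Replaces every pairing probability in a [BasePairMatrix-class] with its
#' log-odds score (see [bpScore()]).  Entries at or below `p0` become exact
#' zeros, so sparsity is preserved (and never decreases as `p0` grows).
#'
#' @param x a [BasePairMatrix-class]
#' @param params a [ScoreParams()] object
#' @return a dense base `matrix` of scores, symmetric with zero diagonal
#' @export
scoreMatrix <- function(x, params = ScoreParams()) {
    stopifnot(methods::is(x, "BasePairMatrix"))
    p <- as.matrix(x@probs)
    s <- matrix(0, nrow(p), ncol(p))
    nz <- p > params@p0
    if (any(nz)) s[nz] <- bpScore(p[nz], params)
    s
}
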