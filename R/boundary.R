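#' BoundaryPrediction: the result of a boundary search
#'
#' Holds the predicted boundaries `[u, v]` of the self-contained structured
#' domain (1-based, inclusive), the method and parameters that produced
#' them, the winning fitness value, and — for the log-space fitness — the
#' three component log-scores.
#'
#' @slot u,v predicted start and end (NA for a no-structure result)
#' @slot method `"rnabound"` or `"dotu"`
#' @slot score winning fitness (log-space for rnabound, linear for dotu)
#' @slot status `"ok"` or `"no-structure"` (every candidate scored -Inf)
#' @slot components named numeric: `logI`, `logO`, `logS` (rnabound only,
#'   otherwise empty)
#' @slot params the parameter object used, as a list
#' @slot frame coordinate frame tag: `"alignment"`, `"reference"` or
#'   `"unspecified"`; compared by [boundaryDifference()]
#' @exportClass BoundaryPrediction
setClass("BoundaryPrediction",
    representation(
        u = "integer", v = "integer",
        method = "character", score = "numeric", status = "character",
        components = "numeric", params = "list", frame = "character"
    )
)

setValidity("BoundaryPrediction", function(object) {
    msg <- character()
    if (object@status == "ok") {
        if (is.na(object@u) || is.na(object@v) || object@u >= object@v)
            msg <- c(msg, "an 'ok' prediction needs u < v")
    }
    if (!object@method %in% c("rnabound", "dotu"))
        msg <- c(msg, "method must be 'rnabound' or 'dotu'")
    if (!object@frame %in% c("alignment", "reference", "unspecified"))
        msg <- c(msg, "frame must be alignment, reference or unspecified")
    if (length(msg)) msg else TRUE
})

#' @describeIn BoundaryPrediction-class predicted `(u, v)` as an integer
#'   vector (NAs for a no-structure result)
#' @param x a `BoundaryPrediction`
#' @export
predictedBoundaries <- function(x) c(u = x@u, v = x@v)

#' @describeIn BoundaryPrediction-class winning fitness value
#' @export
fitnessScore <- function(x) x@score

#' @describeIn BoundaryPrediction-class `"ok"` or `"no-structure"`
#' @export
predictionStatus <- function(x) x@status

#' @describeIn BoundaryPrediction-class the method tag
#' @export
predictionMethod <- function(x) x@method

setMethod("show", "BoundaryPrediction", function(object) {
    if (object@status == "ok") {
        cat(sprintf("BoundaryPrediction (%s): [%d, %d], score %.6g\n",
                    object@method, object@u, object@v, object@score))
        if (length(object@components))
            cat(sprintf("  components: logI = %.4g, logO = %.4g, logS = %.4g\n",
                        object@components[["logI"]], object@components[["logO"]],
                        object@components[["logS"]]))
    } else {
        cat(sprintf("BoundaryPrediction (%s): no structure found\n",
                    object@method))
    }
    cat(sprintf("  frame: %s\n", object@frame))
})

#' @export
setMethod("as.data.frame", "BoundaryPrediction",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(method = x@method, u = x@u, v = x@v, score = x@score,
                   status = x@status, frame = x@frame)
    })

.newPrediction <- function(u, v, method, score, status, components, params,
                           frame) {
    methods::new("BoundaryPrediction",
        u = as.integer(u), v = as.integer(v), method = method,
        score = score, status = status, components = components,
        params = params, frame = frame)
}

#' Log-space segment fitness of a candidate boundary pair
#'
#' Evaluates the three-component self-containment fitness of segment
#' `[k, l]` on a table of base-pair scores (see [scoreMatrix()]).  In log
#' space,
#' \deqn{\log F_{kl} = \log I_{bp} + \log O_{\neg bp} + \log S_{\neg bp},}
#' where
#' \itemize{
#'   \item \eqn{\log I_{bp}} is the mean over segment positions
#'     \eqn{m \in [k,l]} of \eqn{\log \min(1, \sum_{n\in[k,l]} s_{mn})}: the
#'     log geometric mean of per-position in-segment pairing mass;
#'   \item \eqn{\log O_{\neg bp}} is the mean over segment positions of
#'     \eqn{\log(1 - \sum_{n\notin[k,l]} s_{mn})}: the mass *not* crossing
#'     the boundaries;
#'   \item \eqn{\log S_{\neg bp}} is the mean over the upstream margin
#'     \eqn{m \in [k-f, k-1]} of
#'     \eqn{\log(1 - \sum_{n=l+1}^{l+f} s_{mn})}: the mass *not* spanning
#'     the segment between its two flanking margins (0 when `f = 0`).
#' }
#' A zero in-segment sum, or a crossing/spanning sum reaching 1, makes the
#' corresponding log term `-Inf`, disqualifying the segment; no epsilon
#' smoothing is applied.  The in-segment sum is capped at 1 so that every
#' component stays in `[0, 1]` and the log-fitness is bounded above by 0,
#' with equality only for a perfectly self-contained segment.
#'
#' @param scores symmetric numeric score matrix from [scoreMatrix()] (raw
#'   probabilities may be supplied to evaluate the untransformed fitness)
#' @param k,l candidate boundaries, `1 + f <= k < l <= n - f`
#' @param params a [ScoreParams()]; only `f` is used here
#' @param outside optional second matrix used for the crossing and spanning
#'   terms; defaults to `scores`.  Supplying the raw probability matrix
#'   here gives the variant where the score transform applies only inside.
#' @return the log-fitness, a finite number `<= 0` or `-Inf`
#' @export
rnaboundFitness <- function(scores, k, l, params = ScoreParams(),
                            outside = scores) {
    f <- params@f
    n <- nrow(scores)
    if (k < 1L + f || l <= k || l > n - f)
        stop(sprintf("(k, l) = (%d, %d) outside admissible range [%d, %d] with k < l",
                     k, l, 1L + f, n - f))
    seg <- k:l
    inn <- pmin(1, rowSums(scores[seg, seg, drop = FALSE]))
    if (any(inn <= 0)) return(-Inf)
    logI <- mean(log(inn))
    cross <- rowSums(outside[seg, -seg, drop = FALSE])
    remO <- 1 - cross
    if (any(remO <= 0)) return(-Inf)
    logO <- mean(log(remO))
    if (f > 0L) {
        span <- rowSums(outside[(k - f):(k - 1L), (l + 1L):(l + f), drop = FALSE])
        remS <- 1 - span
        if (any(remS <= 0)) return(-Inf)
        logS <- mean(log(remS))
    } else logS <- 0
    logI + logO + logS
}

#' Comparator segment fitness (Dotu et al.)
#'
#' The length-normalised weighted difference between base-pairing
#' probability mass inside a segment and mass crossing its boundaries:
#' \deqn{f_{ij} = \frac{\sum_{i \le x < y \le j} w_1 p_{xy}
#'   - \sum_{x \in [i,j]} \sum_{y \notin [i,j]} w_2 p_{xy}}{j - i + 1}.}
#' Unlike the log-space fitness this operates on raw probabilities, has no
#' flanking-margin term, and needs structure-class-specific weights; the
#' defaults `w1 = 2`, `w2 = 1` were tuned on single-hairpin structures.
#'
#' @param x a [BasePairMatrix-class]
#' @param i,j candidate boundaries, `1 <= i < j <= n`
#' @param params a [DotuParams()]
#' @return the fitness value (any sign)
#' @export
dotuFitness <- function(x, i, j, params = DotuParams()) {
    stopifnot(methods::is(x, "BasePairMatrix"))
    n <- bpLength(x)
    if (i < 1L || j > n || i >= j)
        stop(sprintf("(i, j) = (%d, %d) invalid: need 1 <= i < j <= %d", i, j, n))
    p <- as.matrix(x)
    seg <- i:j
    inside <- sum(p[seg, seg]) / 2
    cross <- sum(p[seg, -seg, drop = FALSE])
    (params@w1 * inside - params@w2 * cross) / (j - i + 1)
}

# Exhaustive scan of the log-space fitness over all admissible (k, l),
# using per-row cumulative sums so each segment costs O(l - k).  Returns
# parallel vectors over segments plus the component terms.
.scanRnabound <- function(S, SO, f) {
    n <- nrow(S)
    if (n < 2L * f + 2L)
        stop(sprintf("window length %d too short for flank f = %d (need >= %d)",
                     n, f, 2L * f + 2L))
    CS <- cbind(0, t(apply(S, 1L, cumsum)))
    CO <- cbind(0, t(apply(SO, 1L, cumsum)))
    totO <- CO[, n + 1L]
    ks <- (f + 1L):(n - f - 1L)
    nseg <- sum((n - f) - ks)
    kv <- integer(nseg); lv <- integer(nseg)
    sc <- numeric(nseg); cI <- numeric(nseg); cO <- numeric(nseg); cS <- numeric(nseg)
    idx <- 0L
    for (k in ks) {
        for (l in (k + 1L):(n - f)) {
            idx <- idx + 1L
            kv[idx] <- k; lv[idx] <- l
            rows <- k:l
            inn <- CS[rows, l + 1L] - CS[rows, k]
            if (min(inn) <= 0) {
                sc[idx] <- -Inf; cI[idx] <- -Inf; cO[idx] <- NA_real_; cS[idx] <- NA_real_
                next
            }
            logI <- mean(log(pmin(1, inn)))
            remO <- 1 - (totO[rows] - (CO[rows, l + 1L] - CO[rows, k]))
            if (min(remO) <= 0) {
                sc[idx] <- -Inf; cI[idx] <- logI; cO[idx] <- -Inf; cS[idx] <- NA_real_
                next
            }
            logO <- mean(log(remO))
            if (f > 0L) {
                fr <- (k - f):(k - 1L)
                remS <- 1 - (CO[fr, l + f + 1L] - CO[fr, l + 1L])
                if (min(remS) <= 0) {
                    sc[idx] <- -Inf; cI[idx] <- logI; cO[idx] <- logO; cS[idx] <- -Inf
                    next
                }
                logS <- mean(log(remS))
            } else logS <- 0
            sc[idx] <- logI + logO + logS
            cI[idx] <- logI; cO[idx] <- logO; cS[idx] <- logS
        }
    }
    list(k = kv, l = lv, score = sc, logI = cI, logO = cO, logS = cS)
}

# Exhaustive scan of the comparator fitness over all (i, j), i < j, using
# 2-D prefix sums: O(n^2) total.
.scanDotu <- function(P, w1, w2) {
    n <- nrow(P)
    if (n < 2L) stop("window length must be at least 2")
    D <- apply(apply(P, 2L, cumsum), 1L, cumsum)  # D[j, i] = sum P[1:i, 1:j]
    D <- t(D)
    Dp <- matrix(0, n + 1L, n + 1L)
    Dp[2:(n + 1L), 2:(n + 1L)] <- D
    rt <- cumsum(rowSums(P))
    rtp <- c(0, rt)
    nseg <- n * (n - 1L) / 2L
    kv <- integer(nseg); lv <- integer(nseg); sc <- numeric(nseg)
    idx <- 0L
    for (i in 1:(n - 1L)) {
        js <- (i + 1L):n
        block <- Dp[cbind(js + 1L, js + 1L)] - Dp[cbind(i, js + 1L)] -
                 Dp[cbind(js + 1L, i)] + Dp[i, i]
        inside <- block / 2
        cross <- (rtp[js + 1L] - rtp[i]) - block
        val <- (w1 * inside - w2 * cross) / (js - i + 1L)
        m <- length(js)
        kv[idx + seq_len(m)] <- i
        lv[idx + seq_len(m)] <- js
        sc[idx + seq_len(m)] <- val
        idx <- idx + m
    }
    list(k = kv, l = lv, score = sc)
}

.scanSegments <- function(x, method, params, transform) {
    if (method == "rnabound") {
        S <- scoreMatrix(x, params)
        SO <- if (transform == "all") S else as.matrix(x)
        .scanRnabound(S, SO, params@f)
    } else {
        .scanDotu(as.matrix(x), params@w1, params@w2)
    }
}

.defaultParams <- function(method, params) {
    if (is.null(params))
        params <- if (method == "rnabound") ScoreParams() else DotuParams()
    wanted <- if (method == "rnabound") "ScoreParams" else "DotuParams"
    if (!methods::is(params, wanted))
        stop(sprintf("method '%s' needs %s parameters", method, wanted))
    methods::validObject(params)
    params
}

#' Find the boundaries of the self-contained structured domain
#'
#' Exhaustively maximises a segment fitness over all admissible boundary
#' pairs and reports the argmax \eqn{[u, v]}.  For `method = "rnabound"`
#' (the log-space three-component fitness) candidates are restricted to
#' `1 + f <= k < l <= n - f` so both flanking margins fit in the window;
#' for `method = "dotu"` every `1 <= i < j <= n` is a candidate.  Ties are
#' broken deterministically towards the smallest start, then the smallest
#' end.  If every candidate scores `-Inf` (possible only for rnabound, e.g.
#' on an empty matrix) a no-structure result is returned, with `NA`
#' coordinates and status `"no-structure"`.
#'
#' @param x a [BasePairMatrix-class]
#' @param method `"rnabound"` (default) or `"dotu"`
#' @param params a [ScoreParams()] or [DotuParams()] matching the method;
#'   `NULL` for the method's defaults
#' @param transform for rnabound only: `"all"` (default) applies the
#'   base-pair score transform in all three fitness components;
#'   `"inside-only"` applies it only to the in-segment term and evaluates
#'   the crossing/spanning terms on raw probabilities
#' @param frame coordinate frame tag carried into the prediction
#' @return a [BoundaryPrediction-class]
#' @examples
#' case <- plantStructure(150, "hairpin", start = 41, end = 90, seed = 1)
#' findBoundaries(caseMatrix(case))
#' @export
findBoundaries <- function(x, method = c("rnabound", "dotu"), params = NULL,
                           transform = c("all", "inside-only"),
                           frame = "unspecified") {
    stopifnot(methods::is(x, "BasePairMatrix"))
    method <- match.arg(method)
    transform <- match.arg(transform)
    params <- .defaultParams(method, params)
    sg <- .scanSegments(x, method, params, transform)
    best <- which.max(sg$score)  # scan order is (k asc, l asc): ties resolve
    if (!length(best) || sg$score[best] == -Inf) {
        return(.newPrediction(NA_integer_, NA_integer_, method, -Inf,
                              "no-structure", numeric(),
                              .paramsAsList(params), frame))
    }
    comp <- if (method == "rnabound")
        c(logI = sg$logI[best], logO = sg$logO[best], logS = sg$logS[best])
    else numeric()
    .newPrediction(sg$k[best], sg$l[best], method, sg$score[best], "ok",
                   comp, .paramsAsList(params), frame)
}

.paramsAsList <- function(params) {
    if (methods::is(params, "ScoreParams"))
        list(p0 = params@p0, f = params@f)
    else
        list(w1 = params@w1, w2 = params@w2)
}

#' Extract non-overlapping sub-optimal segments
#'
#' Greedy extraction of high-fitness non-overlapping segments, for windows
#' that may contain clusters of several self-contained structures: the
#' highest-scoring admissible segment is taken first, then repeatedly the
#' highest-scoring segment separated from every selected one by at least
#' `min_gap - 1` unselected positions, until remaining candidates score
#' `-Inf` (rnabound) or at most 0 (dotu), or `max_segments` is reached.
#'
#' @inheritParams findBoundaries
#' @param min_gap minimum separation in nt between selected segments; the
#'   default 1 demands strict non-overlap (adjacent segments allowed)
#' @param max_segments stop after this many segments
#' @return an [IRanges::IRanges] of selected segments, highest score first,
#'   with a `score` metadata column (empty when nothing qualifies)
#' @export
suboptimalSegments <- function(x, method = c("rnabound", "dotu"), params = NULL,
                               transform = c("all", "inside-only"),
                               min_gap = 1L, max_segments = Inf) {
    stopifnot(methods::is(x, "BasePairMatrix"))
    method <- match.arg(method)
    transform <- match.arg(transform)
    if (min_gap < 1L) stop("min_gap must be at least 1")
    params <- .defaultParams(method, params)
    sg <- .scanSegments(x, method, params, transform)
    keep <- if (method == "rnabound") is.finite(sg$score) else sg$score > 0
    k <- sg$k[keep]; l <- sg$l[keep]; s <- sg$score[keep]
    ord <- order(-s, k, l)
    k <- k[ord]; l <- l[ord]; s <- s[ord]
    selk <- integer(); sell <- integer(); sels <- numeric()
    for (t in seq_along(s)) {
        if (length(selk) >= max_segments) break
        # conflict if expanded intervals intersect: gap < min_gap - 1
        if (!length(selk) ||
            all(k[t] > sell + (min_gap - 1L) | l[t] < selk - (min_gap - 1L))) {
            selk <- c(selk, k[t]); sell <- c(sell, l[t]); sels <- c(sels, s[t])
        }
    }
    out <- IRanges::IRanges(start = selk, end = sell)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(score = sels)
    out
}
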