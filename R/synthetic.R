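#' SyntheticCase: a planted-structure test case
#'
#' A generated base-pairing probability matrix with one planted
#' self-contained structure and known ground-truth boundaries, used to
#' exercise the boundary search end to end without any external folding
#' software.
#'
#' @slot matrix the generated [BasePairMatrix-class] (`source = "synthetic"`)
#' @slot truth planted `(start, end)` boundaries, 1-based inclusive
#' @slot layout `"hairpin"`, `"cloverleaf"` or `"double_hairpin"`
#' @slot stemProb probability assigned to planted stem pairs
#' @slot noiseProb ceiling on background pair probabilities
#' @slot seed RNG seed the case was generated under
#' @slot pairs data frame of all planted pairs `(i, j, p, role)` with
#'   `role` either `"stem"` or `"breathing"`
#' @exportClass SyntheticCase
setClass("SyntheticCase",
    representation(
        matrix = "BasePairMatrix", truth = "integer", layout = "character",
        stemProb = "numeric", noiseProb = "numeric", seed = "integer",
        pairs = "data.frame"
    )
)

#' @describeIn SyntheticCase-class the generated matrix
#' @param x a `SyntheticCase`
#' @export
caseMatrix <- function(x) x@matrix

#' @describeIn SyntheticCase-class planted `(start, end)`
#' @export
caseTruth <- function(x) x@truth

#' @describeIn SyntheticCase-class the planted pair table
#' @export
casePairs <- function(x) x@pairs

setMethod("show", "SyntheticCase", function(object) {
    cat(sprintf("SyntheticCase (%s): n = %d, truth = [%d, %d], seed = %d\n",
                object@layout, bpLength(object@matrix),
                object@truth[1L], object@truth[2L], object@seed))
    cat(sprintf("  %d stem + %d breathing planted pairs, noise ceiling %g\n",
                sum(object@pairs$role == "stem"),
                sum(object@pairs$role == "breathing"), object@noiseProb))
})

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())))
    }
    set.seed(seed)
    expr
}

# Stem pairs (lo+t, hi-t) of a hairpin over [lo, hi], terminal loop >= 3.
.hairpinStem <- function(lo, hi, min_loop = 3L) {
    len <- hi - lo + 1L
    stem <- (len - min_loop) %/% 2L
    if (stem < 2L)
        stop(sprintf("interval [%d, %d] too small for a hairpin stem", lo, hi))
    t <- 0:(stem - 1L)
    cbind(i = lo + t, j = hi - t)
}

.layoutStems <- function(layout, start, end) {
    L <- end - start + 1L
    if (layout == "hairpin") {
        if (L < 7L) stop("hairpin needs end - start + 1 >= 7")
        return(.hairpinStem(start, end))
    }
    if (layout == "double_hairpin") {
        if (L < 24L) stop("double hairpin needs end - start + 1 >= 24")
        hinge <- max(2L, L %/% 20L)
        half <- (L - hinge) %/% 2L
        return(rbind(.hairpinStem(start, start + half - 1L),
                     .hairpinStem(end - half + 1L, end)))
    }
    if (layout == "cloverleaf") {
        if (L < 45L) stop("cloverleaf needs end - start + 1 >= 45")
        acc <- max(3L, min(7L, L %/% 8L))      # acceptor-like closing stem
        inner_lo <- start + acc
        inner_hi <- end - acc
        span <- inner_hi - inner_lo + 1L
        hinge <- 1L
        arm <- (span - 2L * hinge) %/% 3L
        if (arm < 7L) stop("cloverleaf arms too short; enlarge the domain")
        a1 <- c(inner_lo, inner_lo + arm - 1L)
        a2 <- c(a1[2L] + hinge + 1L, a1[2L] + hinge + arm)
        a3lo <- a2[2L] + hinge + 1L
        t <- 0:(acc - 1L)
        return(rbind(cbind(i = start + t, j = end - t),
                     .hairpinStem(a1[1L], a1[2L]),
                     .hairpinStem(a2[1L], a2[2L]),
                     .hairpinStem(a3lo, inner_hi)))
    }
    stop("unknown layout")
}

#' Generate a planted-structure probability matrix
#'
#' Builds a window of length `n` whose only strong pairing signal is one
#' planted self-contained structure over `[start, end]`:
#' \describe{
#'   \item{`hairpin`}{a single stem-loop, miRNA-like;}
#'   \item{`cloverleaf`}{a closing stem plus three internal arms,
#'     tRNA-like (branched);}
#'   \item{`double_hairpin`}{two adjacent stem-loops separated by a short
#'     hinge, H/ACA-snoRNA-like (branched).}
#' }
#' Stem pairs get probability `stem_prob`.  Real Boltzmann ensembles leave
#' no position with exactly zero pairing mass — loops and hinges breathe —
#' so every in-domain position left unpaired by the stems is additionally
#' given one weak in-domain "breathing" pair (probability at most
#' `breathing_prob`, load-capped so no row mass approaches 1, partners at
#' least 4 nt away to respect the minimum hairpin loop).  These breathing
#' pairs are part of the declared planted-pair set.  Background noise
#' pairs are then sprinkled anywhere in the window (`|i - j| >= 4`) with
#' per-cell probability `noise_density` and values drawn uniformly below
#' `noise_prob`; with `noise_prob` at or below the null probability `p0`
#' the noise is invisible to the score transform.
#'
#' Generation is bit-reproducible for a fixed `seed` and leaves the
#' caller's RNG state untouched.
#'
#' @param n window length
#' @param layout `"hairpin"`, `"cloverleaf"` or `"double_hairpin"`
#' @param start,end planted boundaries, `1 <= start < end <= n`
#' @param stem_prob probability of planted stem pairs (default 0.95)
#' @param noise_prob ceiling on background pair probability (default 0:
#'   no noise)
#' @param breathing_prob ceiling on the weak in-domain pairs that give
#'   loop/hinge positions their ensemble mass (default 0.08)
#' @param noise_density expected fraction of eligible background cells
#'   that receive a noise pair (default 0.02)
#' @param seed RNG seed
#' @return a [SyntheticCase-class]
#' @examples
#' case <- plantStructure(150, "hairpin", start = 41, end = 90, seed = 7)
#' predictedBoundaries(findBoundaries(caseMatrix(case)))
#' @export
plantStructure <- function(n, layout = c("hairpin", "cloverleaf", "double_hairpin"),
                           start, end, stem_prob = 0.95, noise_prob = 0,
                           breathing_prob = 0.08, noise_density = 0.02,
                           seed = 1L) {
    layout <- match.arg(layout)
    if (start < 1L || end > n || start >= end)
        stop("need 1 <= start < end <= n")
    if (stem_prob <= 0 || stem_prob > 1) stop("stem_prob must be in (0, 1]")
    if (noise_prob < 0 || noise_prob > 1) stop("noise_prob must be in [0, 1]")
    stems <- .layoutStems(layout, as.integer(start), as.integer(end))
    load <- numeric(n)
    load[stems[, 1L]] <- load[stems[, 1L]] + stem_prob
    load[stems[, 2L]] <- load[stems[, 2L]] + stem_prob
    pairs <- data.frame(i = stems[, 1L], j = stems[, 2L], p = stem_prob,
                        role = "stem")
    # breathing fill: every in-domain position must carry some in-domain mass
    domain <- start:end
    for (x in domain[load[domain] == 0]) {
        if (load[x] > 0) next  # already mass via an earlier breathing pair
        cand <- domain[abs(domain - x) >= 4L]
        cand <- cand[order(load[cand], -abs(cand - x))]
        y <- cand[1L]
        p <- min(breathing_prob, 0.5 * (1 - max(load[x], load[y])))
        pairs <- rbind(pairs, data.frame(i = min(x, y), j = max(x, y), p = p,
                                         role = "breathing"))
        load[x] <- load[x] + p; load[y] <- load[y] + p
    }
    all_pairs <- pairs[, c("i", "j", "p")]
    if (noise_prob > 0) {
        noise <- .withSeed(seed, {
            eli <- which(outer(1:n, 1:n, function(a, b) b - a >= 4L), arr.ind = TRUE)
            hit <- stats::runif(nrow(eli)) < noise_density
            eli <- eli[hit, , drop = FALSE]
            data.frame(i = eli[, 1L], j = eli[, 2L],
                       p = stats::runif(nrow(eli), 0, noise_prob))
        })
        key <- paste(all_pairs$i, all_pairs$j)
        noise <- noise[!paste(noise$i, noise$j) %in% key, , drop = FALSE]
        all_pairs <- rbind(all_pairs, noise)
    }
    m <- BasePairMatrix(all_pairs, n = n, source = "synthetic")
    methods::new("SyntheticCase", matrix = m,
                 truth = c(as.integer(start), as.integer(end)),
                 layout = layout, stemProb = as.numeric(stem_prob),
                 noiseProb = as.numeric(noise_prob), seed = as.integer(seed),
                 pairs = pairs)
}

.CANONICAL <- c("AU", "UA", "GC", "CG", "GU", "UG")

.canPair <- function(a, b) paste0(a, b) %in% .CANONICAL

#' Exact base-pair probabilities of a toy Boltzmann ensemble
#'
#' A minimal partition-function folder for generating realistic-shaped
#' pairing ensembles in tests: every nested secondary structure over the
#' canonical pairs (AU, GC, GU and reverses) with a minimum hairpin loop
#' of 3 nt contributes Boltzmann weight \eqn{w^{\#pairs}} with
#' \eqn{w = e^{-E/kT}}, and exact pair probabilities are obtained by an
#' inside-outside computation.  This is a single per-pair-energy
#' (Nussinov-style) ensemble, not nearest-neighbour thermodynamics: it
#' produces correctly normalised ensembles (every row of the returned
#' matrix sums to at most 1 exactly), not RNAfold's numbers.
#'
#' @param seq RNA string over `A C G U` (T accepted and read as U),
#'   length at least 5
#' @param pair_energy energy per pair in kT-compatible units (default -1;
#'   more negative = stronger pairing)
#' @param kT temperature-like scale (default 1)
#' @return a [BasePairMatrix-class] with `source = "toyfold"`
#' @examples
#' bpPairs(toyFold("GAAAC"))  # single possible pair: p = w / (1 + w)
#' @export
toyFold <- function(seq, pair_energy = -1, kT = 1) {
    s <- strsplit(gsub("T", "U", toupper(seq), fixed = TRUE), "")[[1L]]
    if (length(s) < 5L) stop("sequence must be at least 5 nt")
    if (any(!s %in% c("A", "C", "G", "U")))
        stop("sequence must be over the alphabet A, C, G, U")
    n <- length(s)
    w <- exp(-pair_energy / kT)
    can <- matrix(FALSE, n, n)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n)
        if (j - i >= 4L && .canPair(s[i], s[j])) can[i, j] <- TRUE
    # inside: Z[i, j] over subsequence i..j (1 for empty/short)
    Z <- matrix(1, n + 1L, n + 1L)  # padded so Z[i, j] with j < i reads 1
    zin <- function(i, j) if (j < i) 1 else Z[i, j]
    for (span in 4:(n - 1L)) {
        for (i in 1:(n - span)) {
            j <- i + span
            acc <- zin(i, j - 1L)
            for (h in i:(j - 4L)) {
                if (can[h, j])
                    acc <- acc + zin(i, h - 1L) * w * zin(h + 1L, j - 1L)
            }
            Z[i, j] <- acc
        }
    }
    Ztot <- zin(1L, n)
    # outside: W[i, j] = ensemble weight of everything outside pair (i, j),
    # decomposed on the innermost enclosing pair (computed span-descending
    # so enclosing pairs are ready first)
    plist <- which(can, arr.ind = TRUE)
    if (!nrow(plist))
        return(BasePairMatrix(data.frame(i = integer(), j = integer(),
                                         p = numeric()),
                              n = n, source = "toyfold"))
    plist <- plist[order(-(plist[, 2L] - plist[, 1L])), , drop = FALSE]
    W <- matrix(0, n, n)
    for (t in seq_len(nrow(plist))) {
        i <- plist[t, 1L]; j <- plist[t, 2L]
        acc <- zin(1L, i - 1L) * zin(j + 1L, n)
        if (t > 1L) for (u in 1:(t - 1L)) {
            h <- plist[u, 1L]; l <- plist[u, 2L]
            if (h < i && l > j)
                acc <- acc + w * zin(h + 1L, i - 1L) * zin(j + 1L, l - 1L) * W[h, l]
        }
        W[i, j] <- acc
    }
    idx <- which(can, arr.ind = TRUE)
    p <- vapply(seq_len(nrow(idx)), function(t) {
        i <- idx[t, 1L]; j <- idx[t, 2L]
        w * zin(i + 1L, j - 1L) * W[i, j] / Ztot
    }, numeric(1))
    keep <- p > 0
    BasePairMatrix(data.frame(i = idx[keep, 1L], j = idx[keep, 2L], p = p[keep]),
                   n = n, source = "toyfold")
}

#' Mutate a reference sequence into a toy alignment
#'
#' Generates a gap-free alignment window around a reference sequence, the
#' way homologous structured RNAs diverge: positions covered by planted
#' pairs change *jointly*, swapping the whole pair to a different
#' canonical pair with probability `compensatory_rate` per row (the
#' covariation signal consensus folders exploit), while unpaired positions
#' substitute independently at `sub_rate`.  The reference row is kept
#' verbatim as the first row.
#'
#' @param seq reference RNA string over `A C G U` (T read as U)
#' @param pairs 2-column matrix or data frame of planted pair positions
#'   (disjoint)
#' @param rows total number of rows including the reference (>= 2)
#' @param sub_rate per-position substitution rate at unpaired positions
#'   (default 0.1)
#' @param compensatory_rate per-pair probability of a compensatory double
#'   substitution (default 0)
#' @param seed RNG seed
#' @return an [AlignmentWindow-class] with the reference as row `"ref"`
#' @export
mutateAlignment <- function(seq, pairs, rows, sub_rate = 0.1,
                            compensatory_rate = 0, seed = 1L) {
    s <- strsplit(gsub("T", "U", toupper(seq), fixed = TRUE), "")[[1L]]
    if (any(!s %in% c("A", "C", "G", "U")))
        stop("sequence must be over the alphabet A, C, G, U")
    if (rows < 2L) stop("need at least two rows")
    if (sub_rate < 0 || sub_rate > 1 || compensatory_rate < 0 ||
        compensatory_rate > 1)
        stop("rates must lie in [0, 1]")
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
    if (nrow(pairs) && anyDuplicated(as.vector(pairs)))
        stop("planted pairs must be disjoint")
    paired_pos <- as.vector(pairs)
    unpaired <- setdiff(seq_along(s), paired_pos)
    bases <- c("A", "C", "G", "U")
    out <- .withSeed(seed, {
        lapply(seq_len(rows - 1L), function(r) {
            row <- s
            for (t in seq_len(nrow(pairs))) {
                if (stats::runif(1) < compensatory_rate) {
                    cur <- paste0(row[pairs[t, 1L]], row[pairs[t, 2L]])
                    alt <- setdiff(.CANONICAL, cur)
                    pick <- strsplit(sample(alt, 1L), "")[[1L]]
                    row[pairs[t, 1L]] <- pick[1L]
                    row[pairs[t, 2L]] <- pick[2L]
                }
            }
            mut <- unpaired[stats::runif(length(unpaired)) < sub_rate]
            for (m in mut)
                row[m] <- sample(setdiff(bases, row[m]), 1L)
            paste(row, collapse = "")
        })
    })
    seqs <- c(paste(s, collapse = ""), unlist(out))
    names(seqs) <- c("ref", sprintf("row%02d", seq_len(rows - 1L)))
    AlignmentWindow(seqs, reference = "ref")
}
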