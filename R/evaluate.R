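#' Read and write boundary annotations
#'
#' Annotation tables give the actual boundaries of known structured RNA
#' regions for evaluating predictions.  The on-disk form is a BED-like TSV
#' with columns `id`, `start`, `end`, `family`, `shape_group` and a header
#' pragma declaring the coordinate dialect explicitly (1-based, inclusive)
#' and the coordinate frame, avoiding BED's 0-based half-open ambiguity:
#' \preformatted{# coords: 1-based inclusive
#' # frame: reference}
#'
#' @param file path or connection
#' @return a `data.frame` with columns `id`, `start`, `end`, `family`,
#'   `shape_group` and a `"frame"` attribute
#' @export
readAnnotations <- function(file) {
    lines <- readLines(file, warn = FALSE)
    frame <- "unspecified"
    fr <- grep("^#\\s*frame:", lines, value = TRUE)
    if (length(fr))
        frame <- trimws(sub("^#\\s*frame:", "", fr[1L]))
    body <- lines[!grepl("^\\s*#", lines)]
    d <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
    need <- c("id", "start", "end", "family", "shape_group")
    if (!all(need %in% names(d)))
        stop(sprintf("annotation table must have columns: %s",
                     paste(need, collapse = ", ")))
    if (any(d$start >= d$end))
        stop("annotations must satisfy start < end")
    attr(d, "frame") <- frame
    d
}

#' @rdname readAnnotations
#' @param x annotation `data.frame` (see above)
#' @param frame coordinate frame to declare; defaults to the table's
#'   `"frame"` attribute, else `"unspecified"`
#' @export
writeAnnotations <- function(x, file, frame = NULL) {
    if (is.null(frame))
        frame <- attr(x, "frame") %||% "unspecified"
    header <- c("# coords: 1-based inclusive", sprintf("# frame: %s", frame))
    con <- if (is.character(file)) file(file, "w") else file
    if (is.character(file)) on.exit(close(con))
    writeLines(header, con)
    utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.frameOf <- function(x) {
    if (methods::is(x, "BoundaryPrediction")) return(x@frame)
    attr(x, "frame") %||% "unspecified"
}

#' Signed left/right boundary difference
#'
#' The evaluation metric for predicted boundaries: with actual boundaries
#' `(actual_start, actual_end)` and predicted boundaries `(u, v)`,
#' \deqn{\mathrm{left} = \mathrm{actual\ start} - u, \qquad
#'       \mathrm{right} = v - \mathrm{actual\ end}.}
#' Zero means the boundary was hit exactly; a positive value means the
#' predicted boundary lies outside the annotation (excess); a negative
#' value means it falls inside (short).  Left and right are kept separate
#' and signed — summing or taking absolute values would lose which side
#' failed and in which direction.
#'
#' Both inputs may carry a coordinate-frame tag (`"alignment"` or
#' `"reference"`; a [BoundaryPrediction-class]'s `frame` slot, or a
#' `"frame"` attribute on vectors/data frames).  Two *different* explicit
#' frames are a contract error: differences across frames are meaningless
#' because alignment-column coordinates can exceed the nominal window.
#'
#' @param actual the annotation: numeric `c(start, end)`, or a one-row
#'   data frame with `start`/`end` columns (see [readAnnotations()])
#' @param predicted the prediction: a [BoundaryPrediction-class] or
#'   numeric `c(u, v)`
#' @return named numeric `c(left, right)`
#' @examples
#' boundaryDifference(c(45, 182), c(46, 174))   # left -1, right -8
#' boundaryDifference(c(45, 182), c(127, 162))  # left -82, right -20
#' @export
boundaryDifference <- function(actual, predicted) {
    fa <- .frameOf(actual); fp <- .frameOf(predicted)
    if (fa != "unspecified" && fp != "unspecified" && fa != fp)
        stop(sprintf("coordinate frame mismatch: actual is '%s', predicted is '%s'",
                     fa, fp))
    if (is.data.frame(actual)) {
        stopifnot(nrow(actual) == 1L)
        actual <- c(actual$start, actual$end)
    }
    if (methods::is(predicted, "BoundaryPrediction")) {
        if (predicted@status != "ok")
            stop("cannot score a no-structure prediction")
        predicted <- c(predicted@u, predicted@v)
    }
    stopifnot(length(actual) == 2L, length(predicted) == 2L)
    c(left = actual[[1L]] - predicted[[1L]],
      right = predicted[[2L]] - actual[[2L]])
}

#' Summarise boundary differences by group
#'
#' Median left/right boundary differences (the midpoint-of-two convention
#' for even group sizes), interquartile ranges and group sizes, grouped by
#' any combination of columns (typically `family`, `shape_group` and/or
#' `method`).  Groups with at most `flag_n` members are flagged as small,
#' following the reporting convention of only trusting families with more
#' than five entries.
#'
#' @param diffs a `data.frame` with numeric columns `left` and `right`
#'   plus any grouping columns
#' @param by character vector of grouping column names (default: none —
#'   one overall summary row)
#' @param flag_n groups of size `<= flag_n` get `small_group = TRUE`
#'   (default 5)
#' @return a `data.frame` with one row per group: grouping columns,
#'   `median_left`, `median_right`, `iqr_left`, `iqr_right`, `n`,
#'   `small_group`
#' @export
summarizeDiffs <- function(diffs, by = character(), flag_n = 5L) {
    if (!is.data.frame(diffs) || nrow(diffs) == 0L)
        stop("diffs must be a non-empty data frame")
    if (!all(c("left", "right") %in% names(diffs)))
        stop("diffs must have 'left' and 'right' columns")
    if (!all(by %in% names(diffs)))
        stop("grouping columns missing from diffs")
    key <- if (length(by)) interaction(diffs[by], drop = TRUE, sep = "\r")
           else factor(rep("all", nrow(diffs)))
    rows <- lapply(levels(key), function(lv) {
        g <- diffs[key == lv, , drop = FALSE]
        meta <- if (length(by)) g[1L, by, drop = FALSE]
                else data.frame(row.names = 1L)
        cbind(meta,
              data.frame(median_left = stats::median(g$left),
                         median_right = stats::median(g$right),
                         iqr_left = stats::IQR(g$left),
                         iqr_right = stats::IQR(g$right),
                         n = nrow(g),
                         small_group = nrow(g) <= flag_n))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney rank-sum comparison of two samples, as used to test
#' whether two prediction sets differ in their boundary-difference
#' distributions.  Without ties and with both sample sizes at most 20 the
#' exact null distribution of U is used; otherwise the normal
#' approximation with tie correction and continuity correction.  If the
#' pooled sample is constant the comparison is degenerate and `p = 1` is
#' returned with `degenerate = TRUE`.
#'
#' @param x,y numeric samples
#' @return a list: `statistic` (U for sample `x`), `z` (normal-approximation
#'   score, `NA` on the exact path), `p.value`, `exact` (logical),
#'   `degenerate` (logical)
#' @examples
#' wilcoxonRankSum(1:10, 101:110)$p.value  # 2 / choose(20, 10)
#' @export
wilcoxonRankSum <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    if (!length(x) || !length(y)) stop("both samples must be non-empty")
    if (anyNA(c(x, y))) stop("samples must not contain NA")
    n1 <- length(x); n2 <- length(y); N <- n1 + n2
    pooled <- c(x, y)
    if (length(unique(pooled)) == 1L)
        return(list(statistic = n1 * n2 / 2, z = NA_real_, p.value = 1,
                    exact = FALSE, degenerate = TRUE))
    r <- rank(pooled)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- any(duplicated(pooled))
    if (!ties && max(n1, n2) <= 20L) {
        p <- 2 * min(stats::pwilcox(U, n1, n2),
                     1 - stats::pwilcox(U - 1, n1, n2))
        return(list(statistic = U, z = NA_real_, p.value = min(1, p),
                    exact = TRUE, degenerate = FALSE))
    }
    mu <- n1 * n2 / 2
    tab <- table(r)
    tiecorr <- sum(tab^3 - tab) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * (N + 1 - tiecorr))
    d <- U - mu
    z <- (d - sign(d) * 0.5) / sigma  # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    list(statistic = U, z = z, p.value = min(1, p), exact = FALSE,
         degenerate = FALSE)
}

#' Compare two sets of boundary differences
#'
#' Two-sided Wilcoxon rank-sum comparison of one side (left or right) of
#' the boundary differences produced by two methods or two input
#' conditions (e.g. single sequence vs multiple alignment).
#'
#' @param diffs_a,diffs_b data frames with `left`/`right` columns (as
#'   built from [boundaryDifference()] results), or plain numeric vectors
#' @param side `"left"` or `"right"`; ignored for numeric input
#' @return the [wilcoxonRankSum()] result list, plus `side`
#' @export
compareMethods <- function(diffs_a, diffs_b, side = c("left", "right")) {
    side <- match.arg(side)
    pick <- function(d) {
        if (is.data.frame(d)) {
            if (!side %in% names(d))
                stop(sprintf("column '%s' missing", side))
            d[[side]]
        } else as.numeric(d)
    }
    out <- wilcoxonRankSum(pick(diffs_a), pick(diffs_b))
    out$side <- side
    out
}
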