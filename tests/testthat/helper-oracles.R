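# Independent brute-force oracles and fixture builders.  These deliberately
# re-derive every quantity from the defining formulas with naive loops and
# direct index sets, sharing no code with the package internals.

# Literal three-component segment fitness: geometric means in linear space,
# logged at the end.  'outside' lets the crossing/spanning terms run on a
# different table (raw probabilities) than the inside term.
oracleRnabound <- function(scores, k, l, f, outside = scores) {
  n <- nrow(scores)
  L <- l - k + 1
  inside <- numeric(L)
  for (m in k:l) {
    s <- 0
    for (nn in k:l) s <- s + scores[m, nn]
    inside[m - k + 1] <- min(1, s)
  }
  if (any(inside <= 0)) return(-Inf)
  Ibp <- prod(inside)^(1 / L)
  outmass <- numeric(L)
  for (m in k:l) {
    s <- 0
    for (nn in setdiff(1:n, k:l)) s <- s + outside[m, nn]
    outmass[m - k + 1] <- s
  }
  if (any(1 - outmass <= 0)) return(-Inf)
  Obp <- prod(1 - outmass)^(1 / L)
  if (f > 0) {
    span <- numeric(f)
    for (m in (k - f):(k - 1)) {
      s <- 0
      for (nn in (l + 1):(l + f)) s <- s + outside[m, nn]
      span[m - (k - f) + 1] <- s
    }
    if (any(1 - span <= 0)) return(-Inf)
    Sbp <- prod(1 - span)^(1 / f)
  } else Sbp <- 1
  log(Ibp) + log(Obp) + log(Sbp)
}

# Literal comparator fitness: double loops over the defining index sets.
oracleDotu <- function(P, i, j, w1 = 2, w2 = 1) {
  n <- nrow(P)
  inside <- 0
  for (x in i:j) for (y in i:j) if (x < y) inside <- inside + P[x, y]
  cross <- 0
  for (x in i:j) for (y in setdiff(1:n, i:j)) cross <- cross + P[x, y]
  (w1 * inside - w2 * cross) / (j - i + 1)
}

# Exhaustive enumeration of all nested structures (canonical pairs, minimum
# hairpin loop 3) with Boltzmann weight w^#pairs; returns the exact pair
# probability matrix.  Recursion: either position j is unpaired, or j pairs
# with some h, splitting the interval.
enumFoldProbs <- function(seq, w) {
  s <- strsplit(gsub("T", "U", toupper(seq), fixed = TRUE), "")[[1]]
  n <- length(s)
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  structs <- function(i, j) {
    if (j - i < 4) return(list(list()))  # only the open structure
    out <- lapply(structs(i, j - 1), identity)
    for (h in i:(j - 4)) {
      if (paste0(s[h], s[j]) %in% canonical) {
        left <- structs(i, h - 1)
        mid <- structs(h + 1, j - 1)
        for (a in left) for (b in mid)
          out[[length(out) + 1]] <- c(a, b, list(c(h, j)))
      }
    }
    out
  }
  all <- if (n >= 5) structs(1, n) else list(list())
  P <- matrix(0, n, n)
  Z <- 0
  for (st in all) {
    wt <- w^length(st)
    Z <- Z + wt
    for (pr in st) {
      P[pr[1], pr[2]] <- P[pr[1], pr[2]] + wt
      P[pr[2], pr[1]] <- P[pr[2], pr[1]] + wt
    }
  }
  P / Z
}

# Exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled values to the first sample (no ties assumed).
enumWilcoxP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  U_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  pl <- mean(U_all <= U_obs)
  pu <- mean(U_all >= U_obs)
  min(1, 2 * min(pl, pu))
}

# Random sparse symmetric probability matrix with bounded row mass.
randomSparseBP <- function(n, npairs, seed, pmax = 0.9) {
  set.seed(seed)
  P <- matrix(0, n, n)
  tries <- 0
  placed <- 0
  while (placed < npairs && tries < npairs * 50) {
    tries <- tries + 1
    i <- sample(n - 4, 1)
    j <- sample((i + 4):n, 1)
    p <- runif(1, 0.001, pmax)
    if (P[i, j] == 0 && sum(P[i, ]) + p <= 1 && sum(P[j, ]) + p <= 1) {
      P[i, j] <- p; P[j, i] <- p
      placed <- placed + 1
    }
  }
  BasePairMatrix(P)
}

# Minimal RNAfold-style dot-plot PostScript fixture.
writeDotplotFixture <- function(file, seq = NULL, ubox = NULL, lbox = NULL) {
  lines <- c("%!PS-Adobe-3.0 EPSF-3.0",
             "%%Title: RNA Dot Plot",
             "/DPdict 100 dict def")
  if (!is.null(seq)) {
    chunks <- substring(seq, seq(1, nchar(seq), 60),
                        pmin(seq(60, nchar(seq) + 59, 60), nchar(seq)))
    lines <- c(lines, "/sequence { (\\",
               paste0(chunks, "\\"),
               ") } def")
  }
  lines <- c(lines, "drawgrid")
  if (!is.null(ubox))
    lines <- c(lines, sprintf("%d %d %.12f ubox", ubox[, 1], ubox[, 2], ubox[, 3]))
  if (!is.null(lbox))
    lines <- c(lines, sprintf("%d %d %.8f lbox", lbox[, 1], lbox[, 2], lbox[, 3]))
  lines <- c(lines, "showpage", "%%EOF")
  writeLines(lines, file)
  file
}

# Random RNA sequence.
randomRNA <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
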