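# Brute-force oracles, deliberately independent of the package's
# implementation routes: morphology is checked against explicit Euclidean
# distance classification (the implementation uses shift-accumulate
# dilation), components against a scalar stack-based flood fill, and the
# exact tests against full enumeration of rank assignments/sign patterns.

# Voxels whose minimum Euclidean distance to any target voxel is <= maxDist.
oracleDistanceLE <- function(d, targetIdx, maxDist) {
  out <- array(FALSE, d)
  if (length(targetIdx) == 0L) return(out)
  tco <- arrayInd(targetIdx, d)
  allco <- arrayInd(seq_len(prod(d)), d)
  mind <- rep(Inf, prod(d))
  for (j in seq_len(nrow(tco))) {
    dd <- sqrt(rowSums(sweep(allco, 2, tco[j, ])^2))
    mind <- pmin(mind, dd)
  }
  array(mind <= maxDist + 1e-9, d)
}

# Erosion with the 6-cross by direct neighbourhood check.
oracleErode6 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  offs <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (v in which(mask)) {
    co <- arrayInd(v, d)
    keep <- TRUE
    for (i in seq_len(nrow(offs))) {
      nc <- co + offs[i, ]
      if (any(nc < 1) || any(nc > d)) { keep <- FALSE; break }
      ni <- nc[1] + d[1] * (nc[2] - 1) + d[1] * d[2] * (nc[3] - 1)
      if (!mask[ni]) { keep <- FALSE; break }
    }
    if (keep) out[v] <- TRUE
  }
  out
}

# PL and shells 1-3 of one lesion by distance classification.
oraclePLShells <- function(lesionK, exclUnion, wm) {
  d <- dim(lesionK)
  pl <- oracleDistanceLE(d, which(lesionK), 2) & !exclUnion & wm
  inner <- exclUnion | pl
  s1 <- oracleDistanceLE(d, which(pl), 1) & !inner & wm
  inner <- inner | s1
  s2 <- oracleDistanceLE(d, which(pl), 2) & !inner & wm
  inner <- inner | s2
  s3 <- oracleDistanceLE(d, which(pl), 3) & !inner & wm
  list(pl = pl, shell1 = s1, shell2 = s2, shell3 = s3)
}

# Scalar stack-based flood fill (components in first-voxel order).
oracleFloodFill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[v]) next
      lab[v] <- cur
      co <- arrayInd(v, d)
      for (i in seq_len(nrow(offs))) {
        nc <- co + offs[i, ]
        if (any(nc < 1) || any(nc > d)) next
        ni <- nc[1] + d[1] * (nc[2] - 1) + d[1] * d[2] * (nc[3] - 1)
        if (mask[ni] && !lab[ni]) stack <- c(stack, ni)
      }
    }
  }
  list(labels = lab, count = cur)
}

# Exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1)
# assignments of the pooled values to the first sample.
oracleMWUp <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  uStat <- function(xs, ys) sum(outer(xs, ys, ">"))
  u0 <- uStat(x, y)
  cols <- utils::combn(length(pooled), n1)
  us <- apply(cols, 2, function(ii) uStat(pooled[ii], pooled[-ii]))
  min(1, 2 * min(mean(us <= u0), mean(us >= u0)))
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# patterns of the ranked absolute differences (zeros dropped first).
oracleWSRp <- function(x, y) {
  dff <- x - y
  dff <- dff[dff != 0]
  n <- length(dff)
  if (n == 0L) return(1)
  r <- rank(abs(dff))
  v0 <- sum(r[dff > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(vs <= v0), mean(vs >= v0)))
}

# A small all-WM world with given lesion voxels, for geometry tests.
makeWorld <- function(d, lesionVox = NULL) {
  les <- array(FALSE, d)
  if (!is.null(lesionVox)) {
    lesionVox <- matrix(lesionVox, ncol = 3)
    for (i in seq_len(nrow(lesionVox)))
      les[lesionVox[i, 1], lesionVox[i, 2], lesionVox[i, 3]] <- TRUE
  }
  list(lesion = les, wm = array(TRUE, d), gmProb = array(0, d),
       wmProb = array(1, d))
}

# Constant-valued biomarker panel over a full grid.
constantPanel <- function(d, values) {
  lapply(values, function(v) mrVolume(array(v, d)))
}
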