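# Independent oracles and fixture builders used across the suite. Each
# oracle deliberately takes a different computational route from the
# package implementation it checks.

# Two-pass per-voxel SD: explicit demeaning, then root mean square, one
# voxel at a time via apply().
oracleSDMap <- function(data4d, mask, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  nt <- dim(data4d)[4]
  flat <- matrix(data4d, ncol = nt)[as.vector(mask), , drop = FALSE]
  apply(flat, 1L, function(x) {
    centered <- x - mean(x)
    sqrt(sum(centered^2) / (if (denom == "n-1") nt - 1 else nt))
  })
}

oracleMSSDMap <- function(data4d, mask) {
  nt <- dim(data4d)[4]
  flat <- matrix(data4d, ncol = nt)[as.vector(mask), , drop = FALSE]
  apply(flat, 1L, function(x) mean(diff(x)^2))
}

# Least-squares residuals via the normal equations (the implementation uses
# a QR factorization).
oracleResiduals <- function(X, C) {
  D <- cbind(1, as.matrix(C))
  B <- solve(t(D) %*% D, t(D) %*% X)
  X - D %*% B
}

# Full eigendecomposition route to the PLS saliences: eigenpairs of R R'
# (behavior side) and R' R (voxel side).
oracleSingularValues <- function(R) {
  ev <- eigen(R %*% t(R), symmetric = TRUE)$values
  sqrt(pmax(ev, 0))
}

# Depth-first flood fill with an explicit stack and scalar neighbor loops;
# returns component sizes (sorted) and a label array.
oracleFloodFill <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  manh <- abs(offs$di) + abs(offs$dj) + abs(offs$dk)
  offs <- offs[switch(as.character(connectivity), "6" = manh == 1,
                      "18" = manh <= 2, "26" = rep(TRUE, nrow(offs))), ]
  labels <- array(0L, d)
  lab <- 0L
  for (seedVox in which(mask)) {
    if (labels[seedVox] != 0L) next
    lab <- lab + 1L
    stack <- seedVox
    labels[seedVox] <- lab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        ni <- ci[1] + offs$di[o]; nj <- ci[2] + offs$dj[o]
        nk <- ci[3] + offs$dk[o]
        if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] ||
            nk < 1 || nk > d[3]) next
        lin <- (nk - 1L) * d[1] * d[2] + (nj - 1L) * d[1] + ni
        if (mask[lin] && labels[lin] == 0L) {
          labels[lin] <- lab
          stack <- c(stack, lin)
        }
      }
    }
  }
  labels
}

# Canonical multiset representation of a labeling: for each component the
# sorted voxel indices, order-independent.
componentSets <- function(labels) {
  ids <- setdiff(unique(as.vector(labels)), 0L)
  sets <- lapply(ids, function(i) sort(which(labels == i)))
  sets[order(vapply(sets, `[`, integer(1), 1L))]
}

# A small scan whose voxel series are iid or AR(1) noise.
makeScan <- function(dims = c(6, 6, 6), nt = 20, seed = 1,
                     mask = NULL, ar = 0) {
  set.seed(seed)
  nv <- prod(dims)
  E <- matrix(rnorm(nv * nt), nv, nt)
  X <- E
  if (ar != 0) for (t in 2:nt) X[, t] <- ar * X[, t - 1] + E[, t]
  if (is.null(mask)) mask <- array(TRUE, dims)
  subjectScan(array(X + 100, c(dims, nt)), mask = mask,
              subjectId = sprintf("scan-seed%d", seed))
}
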