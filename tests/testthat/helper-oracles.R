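# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# exhaustive flood-fill labeling over all voxels (pure R, queue-based)
floodFillOracle <- function(maskArr, connectivity = 26) {
  d <- dim(maskArr)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  if (connectivity == 6)
    off <- off[abs(off$dx) + abs(off$dy) + abs(off$dz) == 1, ]
  labels <- array(0L, d)
  nxt <- 0L
  for (start in which(maskArr)) {
    si <- arrayInd(start, d)[1, ]
    if (labels[si[1], si[2], si[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(si)
    labels[si[1], si[2], si[3]] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(off))) {
        nb <- cur + c(off$dx[r], off$dy[r], off$dz[r])
        if (any(nb < 1) || any(nb > d)) next
        if (maskArr[nb[1], nb[2], nb[3]] &&
            labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- nxt
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  labels
}

# canonical partition of a labeling: list of sorted voxel-index vectors
partitionOf <- function(labels) {
  idx <- which(labels > 0L)
  parts <- split(idx, labels[idx])
  unname(parts[order(vapply(parts, min, numeric(1)))])
}

# exhaustive SUVpeak: every region voxel as sphere center, explicit
# per-voxel distance test over the whole grid
suvpeakOracle <- function(values, spacing, regionArr, volumeMl = 1) {
  r <- (3 * volumeMl * 1000 / (4 * pi))^(1 / 3)
  d <- dim(values)
  all <- arrayInd(seq_along(values), d)
  best <- -Inf
  for (lin in which(regionArr)) {
    c0 <- arrayInd(lin, d)[1, ]
    dist2 <- ((all[, 1] - c0[1]) * spacing[1])^2 +
             ((all[, 2] - c0[2]) * spacing[2])^2 +
             ((all[, 3] - c0[3]) * spacing[3])^2
    best <- max(best, mean(values[dist2 <= r^2]))
  }
  best
}

# AUC by exhaustive pairwise concordance counting (ties count 1/2)
aucOracle <- function(pred, outcome) {
  pos <- pred[outcome == 1]; neg <- pred[outcome == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# manual observed-minus-expected log-rank arithmetic
logrankOracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  ets <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ets) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    dd <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + dd * n1 / n
    if (n > 1) V <- V + dd * (n1 / n) * (1 - n1 / n) * (n - dd) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# random binary mask on a common default grid
randomMask <- function(d, p = 0.3) {
  BinaryMask(array(stats::runif(prod(d)) < p, d), spacing = c(2, 2, 2))
}

# standard noise-free separable test phantom: three lesions >= 3 mL,
# one sub-3 mL lesion, one hot physiological region
separablePhantom <- function(shape = c(64, 64, 48), suv = 8) {
  generatePhantom(
    lesions = data.frame(x = c(-40, 30, 0, -20),
                         y = c(-30, 25, 40, 30),
                         z = c(0, 10, -20, 25),
                         diameter = c(20, 28, 36, 12), suv = suv),
    physio = data.frame(x = 40, y = -40, z = 20, diameter = 24, suv = 15),
    shape = shape, fwhm = 0, noiseSd = 0)
}
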