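# Programmatic fixtures shared across the suite.

# solid-color image
constImage <- function(rgb, size = 8) {
  px <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  SliceImage(px)
}

# gray image from an 8-bit luma matrix (keeps luma quantization exact)
grayImage <- function(g8, mask = NULL) {
  g <- g8 / 255
  SliceImage(array(rep(g, 3), dim = c(nrow(g8), ncol(g8), 3)), mask = mask)
}

# white disc of given radius on a black field
discImage <- function(size = 64, radius = 20) {
  rows <- matrix(rep(seq_len(size), times = size), size)
  cols <- matrix(rep(seq_len(size), each = size), size)
  c0 <- (size + 1) / 2
  disc <- (rows - c0)^2 + (cols - c0)^2 <= radius^2
  px <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) px[, , ch] <- disc * 1
  list(image = SliceImage(px), disc = disc)
}

# labeled toy dataset: class signal on the first feature
toyDataset <- function(nPerClass = 30, nClasses = 3, p = 6, sep = 2,
                       seed = 1) {
  withr::with_seed(seed, {
    y <- rep(seq_len(nClasses), each = nPerClass)
    X <- matrix(rnorm(length(y) * p), ncol = p)
    X[, 1] <- X[, 1] + sep * y
    colnames(X) <- paste0("f", seq_len(p))
  })
  LabeledDataset(X, y)
}

# independent oracle: exhaustive average-linkage agglomeration on squared
# Euclidean distances (cluster distance = mean over all cross pairs)
bruteAverageLinkage <- function(x, K) {
  clusters <- as.list(seq_along(x))
  d2 <- function(a, b) mean(outer(x[a], x[b], function(u, v) (u - v)^2))
  while (length(clusters) > K) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dd <- d2(clusters[[i]], clusters[[j]])
      if (dd < bestD) { bestD <- dd; best <- c(j, i) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  lab <- integer(length(x))
  for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
  lab
}

# partitions equal up to label renaming
samePartition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# independent AP oracle: precision/recall over all score thresholds,
# recall-increment integration (assumes distinct scores)
bruteAP <- function(isPos, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  prevR <- 0; ap <- 0
  for (t in th) {
    sel <- scores >= t
    P <- sum(isPos & sel) / sum(sel)
    R <- sum(isPos & sel) / sum(isPos)
    ap <- ap + P * (R - prevR)
    prevR <- R
  }
  ap
}

# circular 0/1 transition count, written independently of the package
bitTransitions <- function(code) {
  bits <- as.integer(intToBits(code))[1:8]
  sum(bits != c(bits[-1], bits[1]))
}
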