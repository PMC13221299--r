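# Independent reference implementations used as oracles.  These are written
# in the most literal way possible (explicit loops, no shared code with the
# package) so that agreement is evidence, not tautology.

# Pearson correlation by the direct sum formula
direct_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force kNN imputation oracle matching the documented distance
# contract: SD-scaled Euclidean over mutually observed features, inflated
# by p / |mutual|; donor mean over the k nearest rows with the target
# observed, ties by row order
oracle_knn <- function(X, k = 5, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  s <- rep(1, p)
  if (scale) {
    for (j in 1:p) {
      v <- stats::sd(X[!is.na(X[, j]), j])
      s[j] <- if (is.finite(v) && v > 0) v else 1
    }
  }
  out <- X
  for (i in 1:n) {
    for (j in 1:p) {
      if (!is.na(X[i, j])) next
      d <- rep(NA_real_, n)
      for (r in 1:n) {
        if (r == i) next
        mutual <- which(!is.na(X[i, ]) & !is.na(X[r, ]))
        if (!length(mutual)) { d[r] <- Inf; next }
        ss <- 0
        for (mj in mutual) ss <- ss + ((X[i, mj] - X[r, mj]) / s[mj])^2
        d[r] <- sqrt(p / length(mutual) * ss)
      }
      donors <- setdiff(which(!is.na(X[, j])), i)
      donors <- donors[order(d[donors], donors)]
      fin <- donors[is.finite(d[donors])]
      use <- if (length(fin)) fin[seq_len(min(k, length(fin)))]
             else donors[seq_len(min(k, length(donors)))]
      out[i, j] <- mean(X[use, j])
    }
  }
  out
}

# O(n^3) Ward agglomeration via the Lance-Williams update on squared
# Euclidean distances; returns cluster labels after cutting at k
oracle_ward <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))^2
  active <- 1:n
  members <- lapply(1:n, identity)
  sizes <- rep(1, n)
  while (length(active) > k) {
    best <- c(NA, NA)
    best_d <- Inf
    for (ai in seq_along(active)) {
      for (bi in seq_along(active)) {
        if (bi <= ai) next
        a <- active[ai]; b <- active[bi]
        if (D[a, b] < best_d) { best_d <- D[a, b]; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    for (c0 in setdiff(active, c(a, b))) {
      na <- sizes[a]; nb <- sizes[b]; nc <- sizes[c0]
      D[a, c0] <- D[c0, a] <-
        ((na + nc) * D[a, c0] + (nb + nc) * D[b, c0] - nc * D[a, b]) /
        (na + nb + nc)
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  labels <- integer(n)
  for (ci in seq_along(active)) labels[members[[active[ci]]]] <- ci
  labels
}

# total within-cluster sum of squares of a labelled partition
partition_wss <- function(X, labels) {
  X <- as.matrix(X)
  total <- 0
  for (l in unique(labels)) {
    M <- X[labels == l, , drop = FALSE]
    total <- total + sum(sweep(M, 2, colMeans(M))^2)
  }
  total
}

# adjusted Rand index from the closed-form contingency computation
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  cij <- sum(tab * (tab - 1) / 2)
  ca <- sum(rowSums(tab) * (rowSums(tab) - 1) / 2)
  cb <- sum(colSums(tab) * (colSums(tab) - 1) / 2)
  cn <- n * (n - 1) / 2
  (cij - ca * cb / cn) / ((ca + cb) / 2 - ca * cb / cn)
}

# random matrix with MCAR holes for imputation tests
random_mcar_matrix <- function(n = 50, p = 6, rate = 0.1) {
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", 1:p)))
  holes <- matrix(runif(n * p) < rate, n, p)
  # keep every row and column partly observed
  for (i in 1:n) if (all(holes[i, ])) holes[i, sample(p, 1)] <- FALSE
  for (j in 1:p) if (all(holes[, j])) holes[sample(n, 1), j] <- FALSE
  X[holes] <- NA
  X
}

# five planted centroids (FMI, MMI, BNI z-space) with pairwise separation
# >= 2 z-units, the fourth being the high-fat / average-muscle profile
separated_centroids <- function() {
  m <- rbind(
    c(-1.5, -1.5, -1.5),
    c( 0.0,  0.0,  0.0),
    c( 1.5,  1.5,  1.5),
    c( 2.2, -0.3, -0.3),
    c(-0.5,  1.8,  1.0))
  colnames(m) <- c("fmi", "mmi", "bni")
  m
}

zcols <- function() paste0("z_", c("bmi", "fmi", "lmi", "mmi", "bni", "twi"))
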