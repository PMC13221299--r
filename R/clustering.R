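#' Prune near-collinear features
#'
#' Groups features whose pairwise absolute Pearson correlation exceeds
#' `threshold`, taking the transitive closure (if A~B and B~C, all three
#' form one group even if |r(A, C)| is below threshold).  Within each group
#' the nominated representative is kept if present, otherwise the first
#' feature by column order.  In body-composition data the lean, muscle and
#' water indices are near-perfectly collinear, so clustering keeps a single
#' representative (muscle, by convention) alongside BMI, fat and bone.
#'
#' @param Z Numeric data frame / matrix of features (z-scores).
#' @param threshold Absolute-correlation threshold in (0, 1), exclusive.
#' @param representative Preferred column to keep in a collinear group;
#'   matched against column names directly and with a `z_` prefix,
#'   case-insensitively.
#' @return Character vector of retained column names, in input order.
#' @export
prune_collinear <- function(Z, threshold = 0.99, representative = "mmi") {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly inside (0, 1)", call. = FALSE)
  }
  Zm <- as.matrix(as.data.frame(Z))
  p <- ncol(Zm)
  if (p < 2) return(colnames(Zm))
  r <- abs(stats::cor(Zm, use = "pairwise.complete.obs"))
  # union-find over the |r| > threshold graph (transitive closure)
  parent <- seq_len(p)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      if (isTRUE(r[i, j] > threshold)) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(p), find, 0L)
  nm <- colnames(Zm)
  matches_rep <- tolower(nm) %in%
    tolower(c(representative, paste0("z_", representative)))
  keep <- logical(p)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    rep_in <- members[matches_rep[members]]
    keep[if (length(rep_in)) rep_in[1] else members[1]] <- TRUE
  }
  nm[keep]
}

new_bc_clusters <- function(labels, centroids, method, ...) {
  structure(list(labels = as.integer(labels), k = nrow(centroids),
                 centroids = centroids, method = method, ...),
            class = "bc_clusters")
}

#' @export
print.bc_clusters <- function(x, ...) {
  cat(sprintf("<bc_clusters> %s, k = %d, n = %d\n", x$method, x$k,
              length(x$labels)))
  print(round(x$centroids, 3))
  invisible(x)
}

cluster_centroid_matrix <- function(Zm, labels, k) {
  cent <- rowsum(Zm, labels) / as.vector(table(factor(labels, 1:k)))
  rownames(cent) <- as.character(seq_len(k))
  cent
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' squared Euclidean distances, cut at `k` clusters.  Merge heights are in
#' squared-distance units.  Cluster labels follow order of first
#' appearance in the data, as cut from the tree; use [canonical_order()]
#' for the substantive labelling.
#'
#' @param Z Numeric data frame / matrix (rows = observations; no missing
#'   values).
#' @param k Number of clusters (`n > k`).
#' @return A `bc_clusters` object with the merge history and heights.
#' @export
ward_cluster <- function(Z, k = 5) {
  Zm <- as.matrix(as.data.frame(Z))
  if (anyNA(Zm)) stop("Z must not contain missing values", call. = FALSE)
  if (nrow(Zm) <= k) stop("need more observations than clusters",
                          call. = FALSE)
  hc <- stats::hclust(stats::dist(Zm)^2, method = "ward.D")
  labels <- stats::cutree(hc, k = k)
  new_bc_clusters(labels, cluster_centroid_matrix(Zm, labels, k), "ward",
                  merge = hc$merge, height = hc$height)
}

# k-means++ seeding: iteratively pick centers with prob ~ squared distance
# to the nearest existing center
kmeanspp_centers <- function(Zm, k) {
  n <- nrow(Zm)
  centers <- matrix(NA_real_, k, ncol(Zm))
  idx <- sample.int(n, 1)
  centers[1, ] <- Zm[idx, ]
  d2 <- rowSums(sweep(Zm, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (sum(d2) > 0) {
      idx <- sample.int(n, 1, prob = d2)
    } else {
      # remaining mass zero: pick any row distinct from current centers
      dup <- apply(Zm, 1, function(r) {
        any(colSums(abs(t(centers[seq_len(j), , drop = FALSE]) - r)) == 0)
      })
      if (all(dup)) stop("fewer distinct points than clusters",
                         call. = FALSE)
      idx <- which(!dup)[1]
    }
    centers[j + 1, ] <- Zm[idx, ]
    d2 <- pmin(d2, rowSums(sweep(Zm, 2, centers[j + 1, ])^2))
  }
  centers
}

#' k-means clustering with k-means++ restarts
#'
#' Lloyd's algorithm started from k-means++ seeds, with `n_init` restarts;
#' the partition with the smallest total within-cluster sum of squares is
#' kept.  Deterministic given `seed`.
#'
#' @inheritParams ward_cluster
#' @param seed Integer seed.
#' @param n_init Number of restarts.
#' @param iter_max Lloyd iterations per restart.
#' @return A `bc_clusters` object with `tot_withinss` and `seed`.
#' @export
kmeans_cluster <- function(Z, k = 5, seed = 1L, n_init = 10,
                           iter_max = 100) {
  Zm <- as.matrix(as.data.frame(Z))
  if (anyNA(Zm)) stop("Z must not contain missing values", call. = FALSE)
  if (nrow(Zm) <= k) stop("need more observations than clusters",
                          call. = FALSE)
  best <- NULL
  withr::with_seed(derive_seed(seed, "kmeans"), {
    for (run in seq_len(n_init)) {
      centers <- kmeanspp_centers(Zm, k)
      km <- suppressWarnings(
        stats::kmeans(Zm, centers = centers, iter.max = iter_max,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  new_bc_clusters(best$cluster,
                  cluster_centroid_matrix(Zm, best$cluster, k), "kmeans",
                  tot_withinss = best$tot.withinss, iter = best$iter,
                  seed = seed)
}

#' Canonical labelling of the five body-composition clusters
#'
#' Relabels a 5-cluster solution to the field's semantic order: the three
#' clusters with the lowest BMI centroids become 1-3 in ascending BMI; of
#' the two highest-BMI clusters, the one with the *higher* muscle (MMI)
#' centroid becomes 4 (uniformly high body composition) and the other
#' becomes 5 (high fat, average muscle — the elevated-risk profile).
#' BMI ties are broken by ascending FMI.
#'
#' @param result A `bc_clusters` with `k = 5` whose centroid columns
#'   include BMI and MMI (and FMI for tie-breaking).
#' @return The relabelled `bc_clusters`.
#' @export
canonical_order <- function(result) {
  stopifnot(inherits(result, "bc_clusters"))
  if (result$k != 5) stop("canonical ordering is defined for k = 5",
                          call. = FALSE)
  cent <- result$centroids
  find_col <- function(what) {
    hit <- grep(paste0("(^|_)", what, "$"), tolower(colnames(cent)))
    if (!length(hit)) stop("centroids lack a ", toupper(what), " column",
                           call. = FALSE)
    hit[1]
  }
  bmi <- cent[, find_col("bmi")]
  mmi <- cent[, find_col("mmi")]
  fmi <- tryCatch(cent[, find_col("fmi")], error = function(e) bmi * 0)
  ord_bmi <- order(bmi, fmi)
  low3 <- ord_bmi[1:3]
  top2 <- ord_bmi[4:5]
  top_ord <- top2[order(-mmi[top2], fmi[top2])]  # higher MMI -> label 4
  new_order <- c(low3, top_ord)                  # old labels in new order
  relabel <- integer(5)
  relabel[new_order] <- 1:5
  out <- result
  out$labels <- relabel[result$labels]
  out$centroids <- cent[new_order, , drop = FALSE]
  rownames(out$centroids) <- as.character(1:5)
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table.  1 for identical partitions (up to
#' label permutation), ~0 for independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must have equal length", call. = FALSE)
  }
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Within-cluster sum of squares across candidate k
#'
#' Elbow-style diagnostic: Ward partitions for each candidate `k` with the
#' total within-cluster sum of squares of each.
#'
#' @param Z Numeric feature matrix.
#' @param k_range Candidate cluster counts.
#' @return Tibble with `k` and `tot_withinss`.
#' @export
cluster_diagnostics <- function(Z, k_range = 2:8) {
  Zm <- as.matrix(as.data.frame(Z))
  rows <- lapply(k_range, function(k) {
    res <- ward_cluster(Zm, k = k)
    wss <- sum(vapply(seq_len(k), function(cc) {
      mem <- Zm[res$labels == cc, , drop = FALSE]
      sum(sweep(mem, 2, colMeans(mem))^2)
    }, 0))
    tibble::tibble(k = k, tot_withinss = wss)
  })
  dplyr::bind_rows(rows)
}
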