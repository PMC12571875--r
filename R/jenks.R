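#' Jenks natural-breaks classification
#'
#' Exact dynamic-programming (Fisher) optimal 1-D partition into `k`
#' classes minimizing the within-class sum of squared deviations. Optimal
#' breaks are invariant to monotone affine transforms of the input.
#'
#' @param x numeric vector.
#' @param k number of classes.
#' @return list: `class` (1-based class per element of `x`, increasing with
#'   value), `breaks` (k-1 upper class boundaries, taken as the maximum of
#'   each lower class), `wss` (within-class sum of squares), `gvf`
#'   (goodness of variance fit, 1 - wss/total_ss).
#' @export
jenks_breaks <- function(x, k) {
  n <- length(x)
  if (k < 1 || k > n) stop_glom("glomscape_parameter_error", "need 1 <= k <= length(x)")
  ord <- order(x)
  xs <- x[ord]
  if (length(unique(xs)) < k) {
    stop_glom("glomscape_degenerate_error",
              "need at least %d distinct values for %d classes", k, k)
  }
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  ssd <- function(i, j) {   # SSD of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in seq_len(n)) cost[1, j] <- ssd(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        best <- Inf; bi <- m
        for (i in m:j) {
          v <- cost[m - 1, i - 1] + ssd(i, j)
          if (v < best) { best <- v; bi <- i }
        }
        cost[m, j] <- best
        back[m, j] <- bi
      }
    }
  }
  # recover class boundaries
  cls_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else back[m, j]
    cls_sorted[i:j] <- m
    j <- i - 1L
  }
  cls <- integer(n)
  cls[ord] <- cls_sorted
  breaks <- vapply(seq_len(k - 1), function(m) max(xs[cls_sorted == m]), numeric(1))
  tot <- ssd(1, n)
  wss <- cost[k, n]
  list(class = cls, breaks = breaks, wss = wss,
       gvf = if (tot > 0) 1 - wss / tot else 0)
}

#' Elbow selection for K-means
#'
#' Runs K-means for k = 1..k_max and picks the elbow of the within-cluster
#' sum-of-squares curve as the k with maximal discrete curvature (second
#' difference) of the log inertia, i.e. where the relative decrease of the
#' inertia curve bends hardest. (The log scale keeps a single huge first
#' drop from masking the true elbow.)
#'
#' @param x numeric matrix of observations.
#' @param k_max largest k considered.
#' @param nstart,iter.max passed to [stats::kmeans()].
#' @param seed integer seed.
#' @return list: `k` (selected), `wss` (vector over k), `fits` (kmeans
#'   objects).
#' @export
kmeans_elbow <- function(x, k_max = 10L, nstart = 10L, iter.max = 50L, seed = 1L) {
  x <- as.matrix(x)
  k_max <- min(k_max, nrow(unique(x)))
  if (k_max < 2) stop_glom("glomscape_parameter_error", "need k_max >= 2 and >= 2 distinct rows")
  set.seed(derive_seed(seed, 5L))
  fits <- vector("list", k_max)
  wss <- numeric(k_max)
  for (k in seq_len(k_max)) {
    fits[[k]] <- kmeans(x, centers = k, nstart = nstart, iter.max = iter.max)
    wss[k] <- fits[[k]]$tot.withinss
  }
  ks <- 2:(k_max - 1)
  lw <- log(pmax(wss, max(wss) * 1e-12))
  curv <- lw[ks - 1] - 2 * lw[ks] + lw[ks + 1]
  k_sel <- ks[which.max(curv)]
  list(k = k_sel, wss = wss, fits = fits)
}
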