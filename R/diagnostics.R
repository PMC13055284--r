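#' Treatment signal-to-noise ratio in an embedding
#'
#' Ratio of the mean Euclidean distance over "between-treatment" pairs
#' (same soil, same day, different treatment) to the mean over
#' "within-treatment" pairs (same soil, same day, same treatment). Values
#' near 1 indicate that treatments are as close to each other as replicates
#' are; larger values indicate treatment-group separation at matched soil
#' and time.
#'
#' By default all qualifying pairs are pooled into single between/within
#' means; `per_stratum = TRUE` instead averages the soil x day stratum
#' ratios' components stratum-by-stratum before the final ratio.
#'
#' @param E an `"embedding"`.
#' @param metadata sample metadata with `sample_id`, `soil`, `treatment`,
#'   `day`.
#' @param per_stratum logical; see above.
#' @return A positive number.
#' @export
snr <- function(E, metadata, per_stratum = FALSE) {
  stopifnot(inherits(E, "embedding"))
  pts <- E$points
  md <- metadata[match(rownames(pts), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata does not cover all samples")
  D <- as.matrix(stats::dist(pts))
  n <- nrow(D)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  same_soil <- md$soil[iu[, 1L]] == md$soil[iu[, 2L]]
  same_day <- md$day[iu[, 1L]] == md$day[iu[, 2L]]
  same_trt <- md$treatment[iu[, 1L]] == md$treatment[iu[, 2L]]
  between <- same_soil & same_day & !same_trt
  within <- same_soil & same_day & same_trt
  if (!any(between) || !any(within)) {
    stop("no qualifying between- or within-treatment pairs")
  }
  dv <- D[upper.tri(D)]
  if (!per_stratum) {
    wmean <- mean(dv[within])
    if (wmean == 0) stop("within-treatment distances are all zero (coincident replicates)")
    return(mean(dv[between]) / wmean)
  }
  strat <- paste(md$soil[iu[, 1L]], md$day[iu[, 1L]])
  bs <- tapply(dv[between], strat[between], mean)
  ws <- tapply(dv[within], strat[within], mean)
  common <- intersect(names(bs), names(ws))
  if (!length(common)) stop("no stratum has both pair kinds")
  if (any(ws[common] == 0)) stop("a stratum has zero within-treatment spread")
  mean(bs[common] / ws[common])
}

#' k-nearest-neighbour distance statistics
#'
#' For each point, the mean Euclidean distance to its `k` nearest
#' neighbours (self excluded); summarised over points as the overall mean
#' (`mean_knn`, local sparsity) and the coefficient of variation
#' (`cv_knn` = population SD / mean, local heterogeneity). With
#' `variant = "kth"` the distance to the k-th neighbour is used instead of
#' the mean over the k nearest.
#'
#' @param E an `"embedding"` or a coordinate matrix.
#' @param k neighbourhood size, `k < n`.
#' @param variant `"mean"` (default) or `"kth"`.
#' @return Named list with `mean_knn` and `cv_knn`.
#' @export
knn_stats <- function(E, k = 5L, variant = c("mean", "kth")) {
  variant <- match.arg(variant)
  pts <- if (inherits(E, "embedding")) E$points else as.matrix(E)
  n <- nrow(pts)
  if (k >= n) stop("k must be smaller than the number of points")
  D <- as.matrix(stats::dist(pts))
  per_point <- vapply(seq_len(n), function(i) {
    d <- sort(D[i, -i], partial = k)[seq_len(k)]
    if (variant == "mean") mean(d) else max(d)
  }, numeric(1))
  m <- mean(per_point)
  if (m == 0) {
    warning("all k-nearest-neighbour distances are zero; CV set to 0")
    return(list(mean_knn = 0, cv_knn = 0))
  }
  # population SD, as a descriptive dispersion of the point cloud
  s <- sqrt(mean((per_point - m)^2))
  list(mean_knn = m, cv_knn = s / m)
}

#' Hopkins clustering-tendency statistic
#'
#' Samples `m` real points without replacement and draws `m` uniform probe
#' points in the axis-aligned bounding box of the data; with `u_i` the
#' distance from each probe to its nearest real point and `w_i` the
#' distance from each sampled real point to its nearest other real point,
#' `H = sum(u) / (sum(u) + sum(w))`. Values near 0.5 indicate spatial
#' randomness; values approaching 1 indicate clustering.
#'
#' @param E an `"embedding"` or coordinate matrix.
#' @param m number of sampled real points and probes (default 50),
#'   `m <= n - 1`.
#' @param seed integer seed.
#' @return A number in `[0, 1]`.
#' @export
hopkins <- function(E, m = 50L, seed = 1L) {
  pts <- if (inherits(E, "embedding")) E$points else as.matrix(E)
  n <- nrow(pts)
  if (m > n - 1L) stop("m must be at most n - 1")
  lo <- apply(pts, 2L, min); hi <- apply(pts, 2L, max)
  if (all(hi - lo == 0)) stop("degenerate bounding box: all points coincide")
  with_seed(substream_seed(seed, "hopkins"), {
    real_idx <- sample.int(n, m)
    probes <- matrix(stats::runif(m * ncol(pts), min = rep(lo, each = m),
                                  max = rep(hi, each = m)), nrow = m)
    u <- vapply(seq_len(m), function(i) {
      sqrt(min(colSums((t(pts) - probes[i, ])^2)))
    }, numeric(1))
    w <- vapply(real_idx, function(i) {
      d2 <- colSums((t(pts) - pts[i, ])^2)
      d2[i] <- Inf
      sqrt(min(d2))
    }, numeric(1))
    sum(u) / (sum(u) + sum(w))
  })
}

#' Diagnostics across an embedding-dimensionality sweep
#'
#' Computes SNR, mean and CV of kNN distance, and the Hopkins statistic
#' for every embedding in a sweep, one row per dimensionality.
#'
#' @param sweep an `"embedding_sweep"` or plain list of embeddings.
#' @param metadata sample metadata (for SNR).
#' @param k kNN neighbourhood size (default 5).
#' @param m Hopkins sample size (default 50).
#' @param seed master seed; Hopkins draws from a per-dimension substream.
#' @return data.frame with columns `dimension`, `snr`, `mean_knn`,
#'   `cv_knn`, `hopkins`, `k`, `m`, `seed`; failed dimensions carry `NA`
#'   and the error message in `note`.
#' @export
sweep_diagnostics <- function(sweep, metadata, k = 5L, m = 50L, seed = 1L) {
  embeddings <- if (inherits(sweep, "embedding_sweep")) sweep$embeddings
                else sweep
  if (!length(embeddings)) stop("no embeddings supplied")
  ids <- sort(rownames(embeddings[[1L]]$points))
  rows <- lapply(embeddings, function(E) {
    if (!identical(sort(rownames(E$points)), ids)) {
      stop("embeddings do not share a common sample set")
    }
    note <- NA_character_
    vals <- tryCatch({
      ks <- knn_stats(E, k)
      list(snr = snr(E, metadata), mean_knn = ks$mean_knn,
           cv_knn = ks$cv_knn,
           hopkins = hopkins(E, m, seed = substream_seed(
             seed, paste0("hopkins_d", E$dimension))))
    }, error = function(e) {
      note <<- conditionMessage(e)
      list(snr = NA_real_, mean_knn = NA_real_, cv_knn = NA_real_,
           hopkins = NA_real_)
    })
    data.frame(dimension = E$dimension, snr = vals$snr,
               mean_knn = vals$mean_knn, cv_knn = vals$cv_knn,
               hopkins = vals$hopkins, k = k, m = m, seed = seed,
               note = note)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
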