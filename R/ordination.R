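#' @title Embedding objects
#' @description Every ordination method in the package returns an
#' `"embedding"`: sample coordinates in `d` dimensions plus method
#' diagnostics (eigenvalues, stress, iteration counts). Coordinates are
#' column-centred and reported under a fixed sign convention (the
#' largest-magnitude entry of each axis is positive) so that repeated runs
#' are directly comparable.
#' @param points samples x d coordinate matrix with sample row names.
#' @param method character label of the producing method.
#' @param diagnostics named list of method diagnostics.
#' @return An object of class `"embedding"` with elements `points`,
#'   `method`, `dimension`, `diagnostics`.
#' @export
new_embedding <- function(points, method, diagnostics = list()) {
  stopifnot(is.matrix(points), all(is.finite(points)), ncol(points) >= 1L)
  pts <- canonicalize_coords(points)
  structure(list(points = pts, method = method, dimension = ncol(pts),
                 diagnostics = diagnostics),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %s, n = %d, d = %d\n", x$method,
              nrow(x$points), x$dimension))
  if (!is.null(x$diagnostics$stress)) {
    cat(sprintf("  stress = %.6g\n", x$diagnostics$stress))
  }
  invisible(x)
}

canonicalize_coords <- function(points) {
  pts <- sweep(points, 2L, colMeans(points))
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (length(i) && pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  pts
}

check_distance_matrix <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 2L)
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("negative dissimilarities")
  invisible(D)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres the squared dissimilarity matrix,
#' `G = -1/2 * J D^2 J` with `J = I - 11'/n`, eigendecomposes it, and
#' returns coordinates scaled by the square roots of the `d` largest
#' positive eigenvalues. On Euclidean input the embedded distances
#' reproduce `D` exactly at full rank. No negative-eigenvalue correction is
#' applied: requesting more axes than there are positive eigenvalues is an
#' explicit error so that infeasible dimensionalities are visible rather
#' than padded.
#'
#' @param D symmetric dissimilarity matrix.
#' @param d number of axes, `d <= n - 1`.
#' @return An `"embedding"`; `diagnostics$eigenvalues` holds the full
#'   spectrum, `diagnostics$positive` the count of positive eigenvalues.
#' @export
pcoa_embed <- function(D, d) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (d > n - 1L) stop("d must be at most n - 1")
  G <- gower_center(D)
  ev <- eigen(G, symmetric = TRUE)
  tol <- max(abs(ev$values)) * 1e-9
  npos <- sum(ev$values > tol)
  if (npos < d) {
    stop(sprintf("only %d positive eigenvalue(s) available; cannot embed in %d dimensions",
                 npos, d))
  }
  pts <- ev$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(d)]), d)
  rownames(pts) <- rownames(D)
  new_embedding(pts, "pcoa",
                diagnostics = list(eigenvalues = ev$values, positive = npos))
}

# Gower double-centering of a dissimilarity matrix: -1/2 J D^2 J.
gower_center <- function(D) {
  A <- -0.5 * D^2
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, ncol(A))) - outer(rep(1, nrow(A)), colMeans(A)) +
    mean(A)
}

sammon_stress <- function(D, delta, csum) {
  sum((D - delta)^2 / D) / csum
}

#' Sammon mapping
#'
#' Minimises the Sammon stress
#' `E = (sum d_ij)^-1 * sum (d_ij - delta_ij)^2 / d_ij`, which weights
#' residuals inversely by the original dissimilarity and therefore
#' emphasises the preservation of small-scale distance relationships.
#' Optimisation is gradient descent with step halving, so the stress trace
#' is non-increasing by construction.
#'
#' @param D symmetric dissimilarity matrix with no zero off-diagonal
#'   entries (the `1/d_ij` weights are undefined for duplicates).
#' @param d target dimensionality.
#' @param init optional starting `"embedding"` or coordinate matrix;
#'   defaults to `pcoa_embed(D, d)`.
#' @param max_iter,tol iteration cap and absolute stress-change tolerance.
#' @param seed integer; only consumed when a random fallback start is
#'   needed, kept for interface uniformity.
#' @return An `"embedding"` with `diagnostics$stress`,
#'   `diagnostics$stress_trace` and `diagnostics$iterations`.
#' @export
sammon_embed <- function(D, d, init = NULL, max_iter = 500L, tol = 1e-9,
                         seed = 1L) {
  check_distance_matrix(D)
  n <- nrow(D)
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    stop("zero off-diagonal dissimilarities; jitter the data or remove duplicate samples before Sammon mapping")
  }
  if (is.null(init)) {
    init <- pcoa_embed(D, d)
  }
  Y <- if (inherits(init, "embedding")) init$points else as.matrix(init)
  stopifnot(nrow(Y) == n, ncol(Y) == d)
  cs <- sum(off)
  Dm <- D; diag(Dm) <- 1  # placeholder; diagonal terms are masked below
  delta <- as.matrix(stats::dist(Y))
  trace <- numeric(0)
  E <- sammon_stress(off, delta[upper.tri(delta)], cs)
  trace <- E
  alpha <- 0.3
  it <- 0L
  repeat {
    it <- it + 1L
    dl <- pmax(delta, 1e-12); diag(dl) <- 1
    W <- (D - delta) / (Dm * dl)
    diag(W) <- 0
    Grad <- (-2 / cs) * (rowSums(W) * Y - W %*% Y)
    gn <- sqrt(sum(Grad^2))
    if (gn == 0) break
    # scale-free step relative to configuration size
    step0 <- alpha * sqrt(sum(Y^2)) / gn
    improved <- FALSE
    st <- step0
    for (h in 1:30) {
      Y2 <- Y - st * Grad
      delta2 <- as.matrix(stats::dist(Y2))
      E2 <- sammon_stress(off, delta2[upper.tri(delta2)], cs)
      if (E2 < E) { improved <- TRUE; break }
      st <- st / 2
    }
    if (!improved) break
    Y <- Y2; delta <- delta2
    dE <- E - E2
    E <- E2
    trace <- c(trace, E)
    alpha <- min(0.5, alpha * if (st == step0) 1.2 else 0.6)
    if (dE < tol || it >= max_iter) break
  }
  rownames(Y) <- rownames(D)
  new_embedding(Y, "sammon",
                diagnostics = list(stress = E, stress_trace = trace,
                                   iterations = it))
}

# Kruskal stress-1 of a configuration given dissimilarity order `ord`
# (indices of the upper-triangle sorted by increasing dissimilarity).
stress1 <- function(delta_vec, ord) {
  fit <- stats::isoreg(delta_vec[ord])$yf
  dhat <- numeric(length(delta_vec))
  dhat[ord] <- fit
  denom <- sum(delta_vec^2)
  if (denom == 0) return(Inf)
  sqrt(sum((delta_vec - dhat)^2) / denom)
}

nmds_descend <- function(off, ord, Y, max_iter, tol = 1e-7) {
  n <- nrow(Y)
  ut <- upper.tri(matrix(0, n, n))
  delta <- as.matrix(stats::dist(Y))
  dv <- delta[ut]
  S <- stress1(dv, ord)
  alpha <- 0.2
  it <- 0L
  while (it < max_iter && S > 1e-9) {
    it <- it + 1L
    # monotone (isotonic) regression of embedded distances on the rank
    # order of the dissimilarities
    fit <- stats::isoreg(dv[ord])$yf
    dhat <- matrix(0, n, n)
    dtmp <- numeric(length(dv)); dtmp[ord] <- fit
    dhat[ut] <- dtmp; dhat <- dhat + t(dhat)
    A <- sum((dv - dtmp)^2); B <- sum(dv^2)
    dl <- pmax(delta, 1e-12); diag(dl) <- 1
    # gradient of S^2 = A/B with dhat held fixed
    W <- 2 * ((delta - dhat) / B - delta * A / B^2) / dl
    diag(W) <- 0
    Grad <- rowSums(W) * Y - W %*% Y
    gn <- sqrt(sum(Grad^2))
    if (gn == 0) break
    st <- alpha * sqrt(sum(Y^2)) / max(gn, 1e-300)
    improved <- FALSE
    for (h in 1:20) {
      Y2 <- Y - st * Grad
      delta2 <- as.matrix(stats::dist(Y2))
      dv2 <- delta2[ut]
      S2 <- stress1(dv2, ord)
      if (S2 < S) { improved <- TRUE; break }
      st <- st / 2
    }
    if (!improved) break
    dS <- S - S2
    Y <- Y2; delta <- delta2; dv <- dv2; S <- S2
    if (dS < tol) break
  }
  list(Y = Y, stress = S, iterations = it)
}

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal's stress-1,
#' `sqrt(sum (delta_ij - dhat_ij)^2 / sum delta_ij^2)`, where `dhat` is the
#' monotone (isotonic) regression of the embedded distances on the rank
#' order of the dissimilarities, so only the rank order of `D` is
#' preserved. A multi-start strategy (one PCoA start plus `n_starts - 1`
#' seeded random starts) guards against local minima; the lowest-stress
#' solution is returned.
#'
#' @param D symmetric dissimilarity matrix; must not be constant.
#' @param d target dimensionality, `n >= d + 1`.
#' @param n_starts total number of starts (>= 1).
#' @param max_iter iteration cap per start.
#' @param seed integer seed for the random starts.
#' @return An `"embedding"` with `diagnostics$stress` (stress-1),
#'   `diagnostics$start` (index of the winning start) and
#'   `diagnostics$iterations`.
#' @export
nmds_embed <- function(D, d, n_starts = 20L, max_iter = 300L, seed = 1L) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (n < d + 1L) stop("need at least d + 1 samples")
  off <- D[upper.tri(D)]
  if (max(off) - min(off) < 1e-15) {
    stop("degenerate dissimilarity matrix: all off-diagonal values equal")
  }
  ord <- order(off)
  starts <- vector("list", n_starts)
  starts[[1L]] <- tryCatch(pcoa_embed(D, d)$points, error = function(e) NULL)
  rscale <- stats::median(off)
  rnd <- with_seed(substream_seed(seed, "nmds_starts"),
                   lapply(seq_len(n_starts), function(i) {
                     matrix(stats::rnorm(n * d, sd = rscale), n, d)
                   }))
  for (i in seq_len(n_starts)) if (is.null(starts[[i]])) starts[[i]] <- rnd[[i]]
  best <- NULL
  for (i in seq_len(n_starts)) {
    res <- nmds_descend(off, ord, starts[[i]], max_iter)
    if (is.null(best) || res$stress < best$stress) {
      best <- res; best$start <- i
    }
  }
  Y <- best$Y
  rownames(Y) <- rownames(D)
  new_embedding(Y, "nmds",
                diagnostics = list(stress = best$stress, start = best$start,
                                   iterations = best$iterations,
                                   n_starts = n_starts))
}

#' Robust Aitchison PCA by masked low-rank matrix completion
#'
#' Applies the rCLR transform (zeros treated as missing) and fits a rank-`d`
#' approximation to the observed entries by iterative SVD imputation:
#' missing entries are initialised at zero, the matrix is decomposed, the
#' missing entries are refilled from the current rank-`d` reconstruction,
#' and the cycle repeats until the Frobenius change of the reconstruction
#' falls below `tol`. Sample scores are the left singular vectors scaled by
#' their singular values.
#'
#' @param table samples x features count matrix.
#' @param d number of components, `d < min(n_samples, n_features)` after
#'   filtering.
#' @param min_feature_count pre-filter threshold (default 8).
#' @param max_iter,tol iteration cap and relative Frobenius tolerance.
#' @param seed kept for interface uniformity; the algorithm is
#'   deterministic given its inputs.
#' @return An `"embedding"` with `diagnostics$converged`,
#'   `diagnostics$iterations` and `diagnostics$singular_values`.
#' @export
rpca_embed <- function(table, d, min_feature_count = 8, max_iter = 500L,
                       tol = 1e-7, seed = 1L) {
  X <- rclr_transform(table, min_feature_count)
  n <- nrow(X); p <- ncol(X)
  if (d >= min(n, p)) {
    stop("d must be smaller than min(n_samples, n_features) = ", min(n, p))
  }
  cm <- complete_low_rank(X, d, max_iter = max_iter, tol = tol)
  pts <- cm$u %*% diag(cm$d, d)
  rownames(pts) <- rownames(X)
  new_embedding(pts, "rpca",
                diagnostics = list(converged = cm$converged,
                                   iterations = cm$iterations,
                                   singular_values = cm$d))
}

# Rank-d completion of a matrix with missing (NA) entries by iterative SVD
# imputation; returns the truncated factors, the completed reconstruction,
# and convergence diagnostics.
complete_low_rank <- function(X, d, max_iter = 500L, tol = 1e-7) {
  miss <- is.na(X)
  Xf <- X; Xf[miss] <- 0
  prev <- NULL
  converged <- FALSE
  it <- 0L
  sv <- NULL
  hat <- NULL
  while (it < max_iter) {
    it <- it + 1L
    sv <- svd(Xf, nu = d, nv = d)
    hat <- sv$u %*% (sv$d[seq_len(d)] * t(sv$v))
    if (!is.null(prev)) {
      rel <- sqrt(sum((hat - prev)^2)) / max(sqrt(sum(prev^2)), 1e-300)
      if (rel < tol) converged <- TRUE
    }
    Xf[miss] <- hat[miss]
    if (converged) break
    prev <- hat
  }
  list(u = sv$u, d = sv$d[seq_len(d)], v = sv$v, reconstruction = hat,
       converged = converged, iterations = it)
}

#' Euclidean distances between embedded samples
#'
#' Reconstructs a sample-by-sample distance matrix from embedding
#' coordinates; used to feed dimension-dependent PERMANOVA with distances
#' derived from rank-`d` ordinations.
#'
#' @param E an `"embedding"`.
#' @return Symmetric Euclidean distance matrix over the embedded samples.
#' @export
reconstruct_distance <- function(E) {
  stopifnot(inherits(E, "embedding"))
  as.matrix(stats::dist(E$points))
}

#' Default dimensionality sweep
#' @export
default_sweep_dims <- function() c(2L, 3L, 4L, 7L, 10L, 15L, 20L, 30L, 70L)

#' Embed at a sweep of dimensionalities
#'
#' Runs one ordination method at each requested dimensionality. Dimensions
#' at which the method fails (e.g. more PCoA axes requested than there are
#' positive eigenvalues) are recorded as skips with the error message
#' rather than aborting the sweep.
#'
#' @param source a distance matrix (for `pcoa`, `sammon`, `nmds`) or a
#'   count table (for `rpca`).
#' @param method one of `"pcoa"`, `"sammon"`, `"nmds"`, `"rpca"`.
#' @param dims strictly increasing integer vector of dimensionalities;
#'   default `c(2, 3, 4, 7, 10, 15, 20, 30, 70)`.
#' @param seed master seed; each dimension draws from its own substream.
#' @param ... further arguments passed to the method.
#' @return An object of class `"embedding_sweep"`: list with `embeddings`
#'   (named `d<k>`) and `skipped` (data.frame of dimension and reason).
#' @export
sweep_embeddings <- function(source, method = c("pcoa", "sammon", "nmds",
                                                "rpca"),
                             dims = default_sweep_dims(), seed = 1L, ...) {
  method <- match.arg(method)
  if (length(dims) == 0L) stop("empty dimensionality sweep")
  if (is.unsorted(dims, strictly = TRUE)) {
    stop("sweep dimensions must be strictly increasing")
  }
  embeddings <- list()
  skipped <- data.frame(dimension = integer(0), reason = character(0))
  for (d in dims) {
    sub <- substream_seed(seed, paste0(method, "_d", d))
    res <- tryCatch({
      switch(method,
             pcoa   = pcoa_embed(source, d),
             sammon = sammon_embed(source, d, seed = sub, ...),
             nmds   = nmds_embed(source, d, seed = sub, ...),
             rpca   = rpca_embed(source, d, seed = sub, ...))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- rbind(skipped,
                       data.frame(dimension = d,
                                  reason = conditionMessage(res)))
    } else {
      embeddings[[paste0("d", d)]] <- res
    }
  }
  structure(list(method = method, embeddings = embeddings, skipped = skipped),
            class = "embedding_sweep")
}
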