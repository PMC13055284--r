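#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a dissimilarity matrix among an
#' ordered list of factors using sequential (Type-I) sums of squares on the
#' Gower-centred matrix, and tests each term's pseudo-F statistic by free
#' permutation of sample labels. The p-value uses the +1 correction,
#' `p = (1 + #{F* >= F}) / (1 + n_perm)`, and therefore never returns 0.
#'
#' @param D symmetric dissimilarity matrix with sample row/col names.
#' @param metadata data.frame with `sample_id` and the factor columns.
#' @param terms ordered character vector of metadata columns to fit
#'   sequentially (default `c("soil", "day", "treatment")`). All terms are
#'   treated as categorical factors.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutations.
#' @return An object of class `"permanova"`: data.frame with one row per
#'   term plus a residual row; columns `term`, `df`, `SS`, `R2`, `F`,
#'   `p_value`; attributes `n_permutations` and `seed`.
#' @export
permanova <- function(D, metadata, terms = c("soil", "day", "treatment"),
                      n_perm = 999L, seed = 1L) {
  check_distance_matrix(D)
  if (n_perm < 99L) stop("use at least 99 permutations")
  n <- nrow(D)
  md <- metadata[match(rownames(D), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("metadata does not cover all samples in D")
  facs <- lapply(terms, function(tm) {
    if (!tm %in% names(md)) stop("unknown term: ", tm)
    f <- factor(md[[tm]])
    if (nlevels(f) < 2L) stop("factor '", tm, "' is constant")
    f
  })
  names(facs) <- terms

  G <- gower_center(D)
  ss_total <- sum(diag(G))

  # Sequential hat matrices: H_k projects onto the column space of the
  # intercept plus the first k factors.
  hats <- vector("list", length(terms))
  M <- matrix(1, n, 1L)
  rank_prev <- 1L
  dfs <- integer(length(terms))
  for (k in seq_along(terms)) {
    M <- cbind(M, stats::model.matrix(~ f - 1, data.frame(f = facs[[k]])))
    q <- qr(M)
    dfs[k] <- q$rank - rank_prev
    rank_prev <- q$rank
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(Q)
  }
  df_res <- n - rank_prev
  if (df_res <= 0L) stop("model saturates the samples; no residual degrees of freedom")

  explained <- function(Gm) {
    tr <- vapply(hats, function(H) sum(H * Gm), numeric(1))
    c(tr[1L], diff(tr))
  }
  ss <- explained(G)
  ss_res <- ss_total - sum(ss)
  Fobs <- (ss / dfs) / (ss_res / df_res)

  exceed <- integer(length(terms))
  # tie guard: permutations that reproduce the observed grouping must count
  # as "as extreme", despite floating-point jitter in the trace contraction
  Fcut <- Fobs - 1e-10 * pmax(1, abs(Fobs))
  with_seed(substream_seed(seed, "permanova"), {
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      Gp <- G[p, p]
      ssp <- explained(Gp)
      Fp <- (ssp / dfs) / ((ss_total - sum(ssp)) / df_res)
      exceed <- exceed + (Fp >= Fcut)
    }
  })
  pval <- (1 + exceed) / (1 + n_perm)

  out <- data.frame(
    term = c(terms, "Residual"),
    df = c(dfs, df_res),
    SS = c(ss, ss_res),
    R2 = c(ss, ss_res) / ss_total,
    F = c(Fobs, NA_real_),
    p_value = c(pval, NA_real_))
  attr(out, "n_permutations") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permanova", "data.frame")
  out
}

#' Dimension-dependent PERMANOVA over an embedding sweep
#'
#' For each embedding in the sweep, reconstructs Euclidean distances from
#' the coordinates and runs (a) the global model with the given ordered
#' terms and (b) a per-soil model with the single `soil_term`, pooling all
#' time points within each soil.
#'
#' @param sweep an `"embedding_sweep"` or plain list of embeddings.
#' @param metadata sample metadata.
#' @param terms global model terms in order.
#' @param soil_term term tested within each soil (default `"treatment"`).
#' @param n_perm,seed permutation parameters.
#' @return data.frame with columns `dimension`, `scope` (`"global"` or the
#'   soil label), `term`, `df`, `R2`, `F`, `p_value`.
#' @export
permanova_sweep <- function(sweep, metadata,
                            terms = c("soil", "day", "treatment"),
                            soil_term = "treatment", n_perm = 999L,
                            seed = 1L) {
  embeddings <- if (inherits(sweep, "embedding_sweep")) sweep$embeddings
                else sweep
  if (!length(embeddings)) stop("no embeddings supplied")
  rows <- list()
  for (E in embeddings) {
    D <- reconstruct_distance(E)
    sub <- substream_seed(seed, paste0("permanova_d", E$dimension))
    gl <- permanova(D, metadata, terms, n_perm, seed = sub)
    keep <- gl$term != "Residual"
    rows[[length(rows) + 1L]] <- data.frame(
      dimension = E$dimension, scope = "global", term = gl$term[keep],
      df = gl$df[keep], R2 = gl$R2[keep], F = gl$F[keep],
      p_value = gl$p_value[keep])
    for (soil in unique(metadata$soil)) {
      sel <- metadata$sample_id[metadata$soil == soil]
      sel <- intersect(rownames(D), sel)
      sw <- tryCatch(
        permanova(D[sel, sel, drop = FALSE],
                  metadata[metadata$sample_id %in% sel, , drop = FALSE],
                  terms = soil_term, n_perm = n_perm,
                  seed = substream_seed(sub, soil)),
        error = function(e) NULL)
      if (is.null(sw)) next
      keep <- sw$term != "Residual"
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = E$dimension, scope = soil, term = sw$term[keep],
        df = sw$df[keep], R2 = sw$R2[keep], F = sw$F[keep],
        p_value = sw$p_value[keep])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise PERMANOVA with Benjamini-Hochberg adjustment
#'
#' Tests every pair of levels of one factor with a two-group PERMANOVA on
#' the corresponding sub-matrix and adjusts the p-values across the family
#' of pairs with the Benjamini-Hochberg procedure.
#'
#' @param D symmetric dissimilarity matrix.
#' @param metadata sample metadata.
#' @param factor_name metadata column to compare pairwise.
#' @param n_perm,seed permutation parameters.
#' @return data.frame with columns `level_a`, `level_b`, `df`, `R2`, `F`,
#'   `p_value`, `q_value`.
#' @export
pairwise_permanova <- function(D, metadata, factor_name, n_perm = 999L,
                               seed = 1L) {
  md <- metadata[match(rownames(D), metadata$sample_id), , drop = FALSE]
  f <- factor(md[[factor_name]])
  if (nlevels(f) < 2L) stop("factor must have at least 2 levels")
  tab <- table(f)
  usable <- names(tab)[tab >= 2L]
  for (lv in setdiff(names(tab), usable)) {
    warning("level '", lv, "' has fewer than 2 samples; skipped")
  }
  prs <- utils::combn(usable, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    lv <- prs[, i]
    sel <- rownames(D)[f %in% lv]
    res <- permanova(D[sel, sel, drop = FALSE],
                     md[md$sample_id %in% sel, , drop = FALSE],
                     terms = factor_name, n_perm = n_perm,
                     seed = substream_seed(seed, paste(lv, collapse = "|")))
    data.frame(level_a = lv[1L], level_b = lv[2L],
               df = res$df[1L], R2 = res$R2[1L], F = res$F[1L],
               p_value = res$p_value[1L])
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Beta dispersion: distance of samples to their group centroid
#'
#' For coordinate input, each sample's Euclidean distance to its group's
#' centroid; for a dissimilarity-matrix input, the samples are first placed
#' in their full-rank principal-coordinates space (all positive-eigenvalue
#' axes) and centroids are taken there.
#'
#' @param x an `"embedding"`, coordinate matrix, or distance matrix.
#' @param groups vector of group labels, one per sample (in row order).
#' @return A list with `samples` (data.frame `sample_id`, `group`,
#'   `distance_to_centroid`) and `group_means` (named numeric).
#' @export
beta_dispersion <- function(x, groups) {
  pts <- if (inherits(x, "embedding")) {
    x$points
  } else if (is.matrix(x) && nrow(x) == ncol(x) &&
             !is.null(rownames(x)) && identical(rownames(x), colnames(x)) &&
             all(diag(x) == 0)) {
    G <- gower_center(x)
    ev <- eigen(G, symmetric = TRUE)
    tol <- max(abs(ev$values)) * 1e-9
    keep <- which(ev$values > tol)
    pts <- ev$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(ev$values[keep]), length(keep))
    rownames(pts) <- rownames(x)
    pts
  } else {
    as.matrix(x)
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(pts))
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 samples")
  }
  dist_to_centroid <- numeric(nrow(pts))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ctr <- colMeans(pts[idx, , drop = FALSE])
    dist_to_centroid[idx] <- sqrt(colSums((t(pts[idx, , drop = FALSE]) -
                                             ctr)^2))
  }
  samples <- data.frame(sample_id = rownames(pts), group = groups,
                        distance_to_centroid = dist_to_centroid)
  gm <- tapply(dist_to_centroid, groups, mean)
  list(samples = samples,
       group_means = stats::setNames(as.numeric(gm), names(gm)))
}

#' Remove features and rescale the remaining community
#'
#' Drops the named feature columns from a count table (e.g. the inoculant
#' taxon) and, by default, rescales every remaining row back to its
#' original total, so the surviving community is "rescaled to 100%":
#' downstream abundance-based analyses then compare compositions rather
#' than sequencing-depth artefacts of the removal. Samples whose total
#' count becomes zero are reported in the `"zero_total_samples"` attribute
#' with a warning (and left at zero).
#'
#' @param table samples x features count matrix.
#' @param feature_ids features to remove; must all be present.
#' @param rescale logical; rescale rows to their pre-removal totals
#'   (default `TRUE`). With `FALSE` the raw reduced counts are returned.
#' @return The reduced (numeric) count matrix.
#' @export
exclude_feature_and_renormalize <- function(table, feature_ids,
                                            rescale = TRUE) {
  stopifnot(is.matrix(table))
  missing <- setdiff(feature_ids, colnames(table))
  if (length(missing)) {
    stop("feature(s) not present: ", paste(missing, collapse = ", "))
  }
  keep <- setdiff(colnames(table), feature_ids)
  if (!length(keep)) stop("removing all features leaves an empty table")
  out <- table[, keep, drop = FALSE]
  rs <- rowSums(out)
  zero <- rownames(out)[rs == 0]
  if (length(zero)) {
    warning("sample(s) left with zero total counts: ",
            paste(zero, collapse = ", "))
  }
  if (rescale) {
    fac <- ifelse(rs > 0, rowSums(table) / pmax(rs, 1), 0)
    out <- out * fac
  }
  attr(out, "zero_total_samples") <- zero
  md <- attr(table, "metadata")
  if (!is.null(md)) attr(out, "metadata") <- md
  out
}

#' Shannon diversity (natural log)
#'
#' `H = -sum p_f log p_f` over the nonzero features of each sample.
#'
#' @param x count vector, or samples x features matrix (row-wise).
#' @return Numeric (per sample for matrix input).
#' @export
shannon <- function(x) {
  one <- function(v) {
    if (sum(v) <= 0) stop("empty sample")
    p <- v[v > 0] / sum(v)
    -sum(p * log(p))
  }
  if (is.matrix(x)) apply(x, 1L, one) else one(x)
}

#' Chao1 richness estimator (bias-corrected when no doubletons)
#'
#' `S_obs + F1^2 / (2 F2)` with singleton count `F1` and doubleton count
#' `F2`; when `F2 = 0` the bias-corrected substitute `F1 (F1 - 1) / 2` is
#' used, so the estimate is always finite and at least `S_obs`.
#'
#' @param x count vector, or samples x features matrix (row-wise).
#' @return Numeric (per sample for matrix input).
#' @export
chao1 <- function(x) {
  one <- function(v) {
    if (sum(v) <= 0) stop("empty sample")
    s_obs <- sum(v > 0)
    f1 <- sum(v == 1); f2 <- sum(v == 2)
    if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  }
  if (is.matrix(x)) apply(x, 1L, one) else one(x)
}

#' Alpha diversity table
#'
#' @param table samples x features count matrix.
#' @return data.frame with `sample_id`, `shannon`, `chao1`.
#' @export
alpha_diversity <- function(table) {
  data.frame(sample_id = rownames(table), shannon = shannon(table),
             chao1 = chao1(table), row.names = NULL)
}
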