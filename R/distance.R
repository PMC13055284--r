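#' Bray-Curtis dissimilarity matrix
#'
#' Computes the abundance-based Bray-Curtis dissimilarity
#' `BC(x, y) = 1 - 2 * sum(min(x, y)) / sum(x + y)` between all pairs of
#' sample rows, on raw counts (no rarefaction or prior normalisation).
#'
#' @param table samples x features count matrix with sample row names.
#' @return Symmetric numeric matrix (samples x samples) with zero diagonal;
#'   values lie in `[0, 1]`.
#' @export
#' @examples
#' m <- rbind(a = c(2, 2), b = c(0, 2))
#' bray_curtis(m)["a", "b"]  # 1/3
bray_curtis <- function(table) {
  stopifnot(is.matrix(table), nrow(table) >= 2L)
  rs <- rowSums(table)
  if (any(rs == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(table)[rs == 0], collapse = ", "))
  }
  n <- nrow(table)
  D <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1L)) {
    xi <- table[i, ]
    for (j in (i + 1L):n) {
      d <- 1 - 2 * sum(pmin(xi, table[j, ])) / (rs[i] + rs[j])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# Branch table of a rooted tree: for every edge, its length and the set of
# leaves below it, encoded as a leaves x edges incidence matrix.
branch_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  children <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    children[[p]] <- c(children[[p]], e)
  }
  inc <- matrix(FALSE, ntip, nrow(tree$edge),
                dimnames = list(tree$tip.label, NULL))
  # postorder accumulation of descendant leaves per edge
  desc <- function(node) {
    if (node <= ntip) return(node)
    out <- integer(0)
    for (e in children[[node]]) {
      tips <- desc(tree$edge[e, 2L])
      inc[tips, e] <<- TRUE
      out <- c(out, tips)
    }
    out
  }
  root <- ntip + 1L
  desc(root)
  inc
}

#' Weighted UniFrac distance matrix
#'
#' For samples with relative-abundance vectors `p`, `q` placed on the leaves
#' of a rooted tree, the raw weighted UniFrac distance is
#' `sum_b l_b * |p_b - q_b|` over branches `b`, where `p_b` is the total
#' relative abundance of the leaves descending from `b`. The normalised
#' variant divides by `sum_b l_b * (p_b + q_b)` and lies in `[0, 1]`.
#'
#' @param table samples x features count matrix; every feature with a
#'   nonzero count must be a leaf of `tree`.
#' @param tree rooted `"phylo"` tree with branch lengths.
#' @param normalized logical; return the normalised variant (default) or
#'   the raw branch-length-weighted form.
#' @return Symmetric distance matrix over samples.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  stopifnot(is.matrix(table), inherits(tree, "phylo"))
  rs <- rowSums(table)
  if (any(rs == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(table)[rs == 0], collapse = ", "))
  }
  used <- colnames(table)[colSums(table) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing)) {
    stop("features absent from tree: ", paste(missing, collapse = ", "))
  }
  inc <- branch_incidence(tree)
  feats <- intersect(colnames(table), rownames(inc))
  rel <- table[, feats, drop = FALSE] / rs
  # per-sample abundance mass below each branch
  mass <- rel %*% (inc[feats, , drop = FALSE] * 1)
  len <- tree$edge.length
  n <- nrow(table)
  D <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      num <- sum(len * abs(mass[i, ] - mass[j, ]))
      if (normalized) {
        den <- sum(len * (mass[i, ] + mass[j, ]))
        D[i, j] <- D[j, i] <- if (den > 0) num / den else 0
      } else {
        D[i, j] <- D[j, i] <- num
      }
    }
  }
  D
}

#' Robust centred log-ratio (rCLR) transform
#'
#' Applies the low-count feature filter, then log-transforms each observed
#' (nonzero) count and centres it by the mean log-count over that sample's
#' observed features. Zero counts are treated as missing (`NA`) rather than
#' imputed, which is what makes the transform robust to compositional
#' zeros.
#'
#' @param table samples x features count matrix.
#' @param min_feature_count features with a smaller total count across all
#'   samples are removed before transforming (default 8).
#' @return Numeric matrix of the same sample set with `NA` exactly where
#'   the count was zero; each row's observed entries sum to zero.
#' @export
rclr_transform <- function(table, min_feature_count = 8) {
  stopifnot(is.matrix(table))
  tab <- apply_min_count_filter(table, min_feature_count)
  if (ncol(tab) == 0L) stop("no features left after the count filter")
  obs <- tab > 0
  if (any(rowSums(obs) == 0L)) {
    stop("sample(s) with no observed features after filtering: ",
         paste(rownames(tab)[rowSums(obs) == 0L], collapse = ", "))
  }
  lg <- suppressWarnings(log(tab))
  lg[!obs] <- NA_real_
  lg - rowMeans(lg, na.rm = TRUE)
}
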