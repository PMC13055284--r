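#' Build per-replicate trajectories from an embedding
#'
#' Groups embedded samples by (soil, treatment, replicate) and orders each
#' group's coordinates by sampling day, yielding one temporal trajectory
#' per replicate microcosm.
#'
#' @param E an `"embedding"` whose row names are sample identifiers.
#' @param metadata data.frame with columns `sample_id`, `soil`,
#'   `treatment`, `day`, `replicate` covering the embedded samples.
#' @return A list of `"trajectory"` objects: each has `soil`, `treatment`,
#'   `replicate`, `days` (increasing) and `coords` (days x d matrix).
#' @export
build_trajectories <- function(E, metadata) {
  stopifnot(inherits(E, "embedding"), is.data.frame(metadata))
  pts <- E$points
  md <- metadata[match(rownames(pts), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) {
    stop("metadata is missing embedded sample(s): ",
         paste(setdiff(rownames(pts), metadata$sample_id), collapse = ", "))
  }
  key <- interaction(md$soil, md$treatment, md$replicate, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    idx <- which(key == k)
    days <- md$day[idx]
    if (anyDuplicated(days)) {
      stop("duplicate (replicate, day) combination in group ", k)
    }
    if (length(idx) < 2L) {
      stop("replicate group ", k, " has a single time point")
    }
    o <- order(days)
    out[[k]] <- structure(
      list(soil = md$soil[idx[1L]], treatment = md$treatment[idx[1L]],
           replicate = md$replicate[idx[1L]], days = days[o],
           coords = pts[idx[o], , drop = FALSE]),
      class = "trajectory")
  }
  out
}

#' Displacement vector of a trajectory between two sampling days
#'
#' @param t a `"trajectory"`.
#' @param from_day,to_day days present in the trajectory.
#' @return Numeric vector `coordinate(to_day) - coordinate(from_day)`.
#' @export
trajectory_vector <- function(t, from_day, to_day) {
  stopifnot(inherits(t, "trajectory"))
  i <- match(from_day, t$days)
  j <- match(to_day, t$days)
  if (is.na(i) || is.na(j)) {
    stop("day(s) absent from trajectory: ",
         paste(c(from_day, to_day)[is.na(c(i, j))], collapse = ", "))
  }
  t$coords[j, ] - t$coords[i, ]
}

#' Cosine of the angle between two vectors
#'
#' `cos(theta) = u . v / (|u| |v|)`: 1 for identical orientation, 0 for
#' orthogonal vectors, -1 for opposite orientations. The result is clamped
#' into `[-1, 1]` against floating-point rounding.
#'
#' @param u,v numeric vectors of equal length with nonzero norm.
#' @return A number in `[-1, 1]`.
#' @export
#' @examples
#' cos_theta(c(1, 0), c(2, 0))   #  1
#' cos_theta(c(1, 0), c(0, 3))   #  0
#' cos_theta(c(1, 1), c(-2, -2)) # -1
cos_theta <- function(u, v) {
  stopifnot(length(u) == length(v))
  n2u <- sum(u^2); n2v <- sum(v^2)
  if (n2u == 0 || n2v == 0) stop("cosine undefined for a zero-norm vector")
  max(-1, min(1, sum(u * v) / sqrt(n2u * n2v)))
}

#' Compare control vs inoculated trajectory directions within a soil
#'
#' Computes the displacement vector of every trajectory of the soil over
#' `[from_day, to_day]` and the cosine similarity for every
#' control x inoculated replicate pair (all-vs-all pairing), reporting the
#' individual values with their arithmetic mean and standard deviation.
#' Replicates missing either endpoint day are excluded with a warning.
#'
#' @param trajs list of trajectories from [build_trajectories()].
#' @param soil soil label to compare within.
#' @param from_day,to_day interval endpoints.
#' @param control_label,inoculated_label treatment labels.
#' @return A list of class `"trajectory_comparison"` with `soil`,
#'   `interval`, `pairs` (data.frame of control, inoculated, cos_theta),
#'   `mean`, `sd`.
#' @export
compare_treatment_trajectories <- function(trajs, soil, from_day, to_day,
                                           control_label = "control",
                                           inoculated_label = "inoculated") {
  sel <- Filter(function(t) t$soil == soil, trajs)
  if (!length(sel)) stop("no trajectories for soil ", soil)
  vecs <- list(); grp <- character(0); rep_ <- integer(0)
  for (t in sel) {
    v <- tryCatch(trajectory_vector(t, from_day, to_day),
                  error = function(e) NULL)
    if (is.null(v)) {
      warning(sprintf("replicate %s/%s/%d lacks day %s or %s; excluded",
                      t$soil, t$treatment, t$replicate, from_day, to_day))
      next
    }
    vecs[[length(vecs) + 1L]] <- v
    grp <- c(grp, t$treatment); rep_ <- c(rep_, t$replicate)
  }
  ic <- which(grp == control_label)
  ii <- which(grp == inoculated_label)
  if (!length(ic) || !length(ii)) {
    stop("need at least one control and one inoculated trajectory with both endpoint days")
  }
  pairs <- expand.grid(control = ic, inoculated = ii)
  ct <- mapply(function(a, b) cos_theta(vecs[[a]], vecs[[b]]),
               pairs$control, pairs$inoculated)
  res <- data.frame(control_replicate = rep_[pairs$control],
                    inoculated_replicate = rep_[pairs$inoculated],
                    cos_theta = ct)
  structure(list(soil = soil,
                 interval = sprintf("%s-%s", from_day, to_day),
                 pairs = res, mean = mean(ct),
                 sd = if (length(ct) > 1L) stats::sd(ct) else 0),
            class = "trajectory_comparison")
}

trajectory_segments <- function(t) {
  k <- nrow(t$coords)
  segs <- t$coords[-1L, , drop = FALSE] - t$coords[-k, , drop = FALSE]
  lens <- sqrt(rowSums(segs^2))
  list(segments = segs, lengths = lens)
}

#' Trajectory smoothness
#'
#' Mean cosine similarity between successive trajectory segments (adjacent
#' time intervals): 1 for a perfectly straight monotone path, negative
#' values for paths that repeatedly reverse direction.
#'
#' @param t a `"trajectory"` with at least 3 time points.
#' @return A number in `[-1, 1]`.
#' @export
smoothness <- function(t) {
  stopifnot(inherits(t, "trajectory"))
  if (nrow(t$coords) < 3L) stop("smoothness needs at least 3 time points")
  sg <- trajectory_segments(t)
  if (any(sg$lengths == 0)) stop("zero-length trajectory segment")
  k <- nrow(sg$segments)
  mean(vapply(seq_len(k - 1L), function(i) {
    cos_theta(sg$segments[i, ], sg$segments[i + 1L, ])
  }, numeric(1)))
}

#' Trajectory linearity
#'
#' Ratio of the net displacement (Euclidean distance between the first and
#' last time point) to the cumulative path length over all segments; 1 for
#' a straight monotone path, 0 for a closed loop.
#'
#' @param t a `"trajectory"`.
#' @return A number in `[0, 1]`.
#' @export
linearity <- function(t) {
  stopifnot(inherits(t, "trajectory"))
  sg <- trajectory_segments(t)
  total <- sum(sg$lengths)
  if (total == 0) stop("zero cumulative path length")
  net <- sqrt(sum((t$coords[nrow(t$coords), ] - t$coords[1L, ])^2))
  net / total
}

#' Trajectory metrics across an embedding-dimensionality sweep
#'
#' For each embedding dimensionality, each soil, and each requested
#' interval, computes the mean and SD of pairwise control-vs-inoculated
#' cosine similarity, and per-trajectory smoothness and linearity.
#'
#' @param sweep an `"embedding_sweep"` (or plain list of embeddings).
#' @param metadata sample metadata (see [build_trajectories()]).
#' @param intervals list of `c(from, to)` day pairs; default is the single
#'   global interval from the first to the last day observed.
#' @param control_label,inoculated_label treatment labels.
#' @return A long-format data.frame with columns `dimension`, `soil`,
#'   `interval`, `metric`, `id`, `value`.
#' @export
sweep_trajectory_metrics <- function(sweep, metadata, intervals = NULL,
                                     control_label = "control",
                                     inoculated_label = "inoculated") {
  embeddings <- if (inherits(sweep, "embedding_sweep")) sweep$embeddings
                else sweep
  if (!length(embeddings)) stop("no embeddings supplied")
  ids <- rownames(embeddings[[1L]]$points)
  for (E in embeddings) {
    if (!identical(sort(rownames(E$points)), sort(ids))) {
      stop("embeddings do not share a common sample set")
    }
  }
  if (is.null(intervals)) {
    days <- sort(unique(metadata$day))
    intervals <- list(c(days[1L], days[length(days)]))
  }
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
  for (E in embeddings) {
    ddim <- E$dimension
    trajs <- build_trajectories(E, metadata)
    for (soil in unique(metadata$soil)) {
      for (iv in intervals) {
        cmp <- compare_treatment_trajectories(trajs, soil, iv[1L], iv[2L],
                                              control_label,
                                              inoculated_label)
        add(dimension = ddim, soil = soil, interval = cmp$interval,
            metric = "cos_theta_mean", id = "summary", value = cmp$mean)
        add(dimension = ddim, soil = soil, interval = cmp$interval,
            metric = "cos_theta_sd", id = "summary", value = cmp$sd)
      }
      for (t in Filter(function(t) t$soil == soil, trajs)) {
        id <- sprintf("%s_r%d", t$treatment, t$replicate)
        if (nrow(t$coords) >= 3L) {
          add(dimension = ddim, soil = soil, interval = "global",
              metric = "smoothness", id = id, value = smoothness(t))
        }
        add(dimension = ddim, soil = soil, interval = "global",
            metric = "linearity", id = id, value = linearity(t))
      }
    }
  }
  do.call(rbind, rows)
}
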