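#' Describe a factorial microcosm sampling design
#'
#' A design specifies the full factorial layout of a soil-microcosm
#' experiment: which soils are incubated, which inoculation treatments are
#' applied, how many replicate microcosms each soil x treatment cell has,
#' and on which days the communities are sampled. The default reproduces a
#' 3 soils x 2 treatments x 3 replicates x 5 days layout (90 samples).
#'
#' @param soils character vector of soil labels.
#' @param treatments character vector of treatment labels; the label given
#'   in `inoculated_label` (default `"inoculated"`) is the one that receives
#'   the inoculant and treatment effects in [generate_counts()].
#' @param replicates integer, replicate microcosms per soil x treatment cell.
#' @param days strictly increasing integer vector of sampling days.
#' @param n_features number of taxa (features) in the simulated community.
#' @param library_size expected sequencing depth (counts) per sample.
#' @param seed master seed for all draws derived from this design.
#' @param inoculated_label which treatment level carries the inoculant.
#' @return An object of class `"design_spec"`.
#' @export
#' @examples
#' d <- design_spec()
#' nrow(generate_metadata(d))  # 90
design_spec <- function(soils = c("ANT", "AT", "G"),
                        treatments = c("control", "inoculated"),
                        replicates = 3L,
                        days = c(0L, 14L, 28L, 57L, 249L),
                        n_features = 500L,
                        library_size = 1e5,
                        seed = 1L,
                        inoculated_label = "inoculated") {
  if (anyDuplicated(soils)) stop("duplicated soil labels in design")
  if (anyDuplicated(treatments)) stop("duplicated treatment labels in design")
  if (anyDuplicated(days)) stop("duplicated days in design")
  stopifnot(replicates >= 1L, n_features >= 2L, library_size >= 1)
  if (is.unsorted(days, strictly = TRUE)) {
    stop("days must be strictly increasing")
  }
  if (!inoculated_label %in% treatments && length(treatments) > 1L) {
    stop("inoculated_label must be one of the treatment levels")
  }
  structure(
    list(soils = as.character(soils), treatments = as.character(treatments),
         replicates = as.integer(replicates), days = as.integer(days),
         n_features = as.integer(n_features), library_size = library_size,
         seed = as.integer(seed), inoculated_label = inoculated_label),
    class = "design_spec")
}

default_feature_ids <- function(n) sprintf("OTU_%04d", seq_len(n))

#' Describe the biological effect structure of a simulated microcosm
#'
#' The generator composes, per sample, a soil-specific baseline composition,
#' a day-scaled temporal drift in log-composition space (shared between
#' treatments, optionally rotated for inoculated microcosms to emulate a
#' divergent response), a constant treatment shift for inoculated samples,
#' and an inoculant taxon whose relative abundance is spiked at the first
#' sampling day and decays log-linearly in time to a soil-specific residual
#' fraction. Residual-fraction defaults follow the soil ordering reported
#' for long-term inoculant persistence: highest in G (0.33%), intermediate
#' in AT (0.17%), lowest in ANT (0.05%).
#'
#' @param design a [design_spec()].
#' @param soil_baseline_concentration named list (by soil) of Dirichlet
#'   concentration vectors of length `n_features`; the normalised vector is
#'   the soil's expected baseline composition. Default: heavy-tailed
#'   log-normal profiles drawn from the design seed, one per soil.
#' @param drift_scale magnitude (log-composition norm) of the temporal drift
#'   reached at the final day; per-day magnitudes scale as
#'   `sqrt(day / max(day))`.
#' @param treatment_shift named numeric (by soil): norm of the constant
#'   log-composition shift applied to inoculated samples. 0 disables it.
#' @param divergence_angle named numeric (by soil), radians: angle by which
#'   the inoculated drift direction is rotated away from the control drift
#'   direction, emulating soil-specific trajectory divergence.
#' @param inoculant_feature_id feature carrying the inoculant; must be one
#'   of the generated feature identifiers.
#' @param inoculant_initial_fraction relative abundance of the inoculant in
#'   inoculated samples at the first sampling day.
#' @param inoculant_residual_fraction named numeric (by soil): relative
#'   abundance at the final sampling day; must not exceed the initial
#'   fraction.
#' @param overdispersion Dirichlet-multinomial precision; larger values give
#'   tighter replicate noise.
#' @return An object of class `"effect_spec"`.
#' @export
effect_spec <- function(design,
                        soil_baseline_concentration = NULL,
                        drift_scale = 16,
                        treatment_shift = NULL,
                        divergence_angle = NULL,
                        inoculant_feature_id = NULL,
                        inoculant_initial_fraction = 0.05,
                        inoculant_residual_fraction = NULL,
                        overdispersion = 200) {
  stopifnot(inherits(design, "design_spec"), overdispersion > 0,
            inoculant_initial_fraction >= 0, inoculant_initial_fraction <= 1)
  soils <- design$soils
  p <- design$n_features
  feats <- default_feature_ids(p)

  if (is.null(inoculant_feature_id)) inoculant_feature_id <- feats[1L]
  if (!inoculant_feature_id %in% feats) {
    stop("inoculant feature '", inoculant_feature_id,
         "' is not among the design's features")
  }

  if (is.null(soil_baseline_concentration)) {
    # shared heavy-tailed core profile plus a per-soil deviation: soils are
    # clearly distinct but share their dominant taxa, as field soils do
    soil_baseline_concentration <- with_seed(
      substream_seed(design$seed, "baseline"), {
        core <- stats::rnorm(p, mean = 0, sd = 2)
        stats::setNames(lapply(soils, function(s) {
          a <- exp(core + stats::rnorm(p, mean = 0, sd = 1.2))
          names(a) <- feats
          a
        }), soils)
      })
  }
  stopifnot(all(soils %in% names(soil_baseline_concentration)))

  fill_soil <- function(x, default) {
    if (is.null(x)) x <- default
    if (is.null(names(x))) x <- stats::setNames(rep_len(x, length(soils)), soils)
    stopifnot(all(soils %in% names(x)))
    x[soils]
  }
  # Divergence defaults emulate nearly parallel control/inoculated drift in
  # two soils and a clearly divergent one in the third (G).
  div_default <- stats::setNames(rep(0, length(soils)), soils)
  for (s in intersect(soils, c("ANT", "AT", "G"))) {
    div_default[s] <- c(ANT = 0.20, AT = 0.28, G = 1.25)[[s]]
  }
  res_default <- stats::setNames(rep(0.002, length(soils)), soils)
  for (s in intersect(soils, c("ANT", "AT", "G"))) {
    res_default[s] <- c(ANT = 0.0005, AT = 0.0017, G = 0.0033)[[s]]
  }

  treatment_shift <- fill_soil(treatment_shift, 0.8)
  divergence_angle <- fill_soil(divergence_angle, div_default)
  inoculant_residual_fraction <- fill_soil(inoculant_residual_fraction,
                                           res_default)
  if (any(inoculant_residual_fraction < 0) ||
      any(inoculant_residual_fraction > 1)) {
    stop("residual fractions must lie in [0, 1]")
  }
  if (any(inoculant_residual_fraction > inoculant_initial_fraction)) {
    stop("residual inoculant fraction exceeds the initial fraction")
  }

  structure(
    list(soil_baseline_concentration = soil_baseline_concentration,
         drift_scale = drift_scale,
         treatment_shift = treatment_shift,
         divergence_angle = divergence_angle,
         inoculant_feature_id = inoculant_feature_id,
         inoculant_initial_fraction = inoculant_initial_fraction,
         inoculant_residual_fraction = inoculant_residual_fraction,
         overdispersion = overdispersion),
    class = "effect_spec")
}

#' Instantiate the sample metadata of a factorial design
#'
#' @param design a [design_spec()].
#' @return A data.frame with columns `sample_id`, `soil`, `treatment`,
#'   `day`, `replicate`, one row per soil x treatment x replicate x day,
#'   in deterministic order.
#' @export
generate_metadata <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  md <- expand.grid(day = design$days,
                    replicate = seq_len(design$replicates),
                    treatment = design$treatments,
                    soil = design$soils,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  md <- md[, c("soil", "treatment", "replicate", "day")]
  md$sample_id <- sprintf("%s_%s_r%d_d%d", md$soil, md$treatment,
                          md$replicate, md$day)
  rownames(md) <- NULL
  md[, c("sample_id", "soil", "treatment", "day", "replicate")]
}

#' Simulate a random rooted phylogeny for the simulated taxa
#'
#' Builds a coalescent-style rooted binary tree over the feature set:
#' lineages are merged in random pairs with exponentially distributed
#' waiting times between merge events, giving an ultrametric-like tree with
#' non-negative branch lengths. The same seed yields a byte-identical
#' Newick string.
#'
#' @param n_features number of leaves (>= 2).
#' @param seed integer seed.
#' @param feature_ids optional leaf labels; default `OTU_0001` ...
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
generate_tree <- function(n_features, seed = 1L, feature_ids = NULL) {
  if (n_features < 2L) stop("a tree needs at least 2 leaves")
  if (is.null(feature_ids)) feature_ids <- default_feature_ids(n_features)
  stopifnot(length(feature_ids) == n_features,
            !anyDuplicated(feature_ids))
  nwk <- with_seed(substream_seed(seed, "tree"), {
    lab <- feature_ids
    height <- rep(0, n_features)
    str <- lab
    h <- 0
    while (length(str) > 1L) {
      k <- length(str)
      h <- h + stats::rexp(1, rate = choose(k, 2))
      pair <- sample.int(k, 2L)
      i <- pair[1L]; j <- pair[2L]
      merged <- sprintf("(%s:%.10g,%s:%.10g)", str[i], h - height[i],
                        str[j], h - height[j])
      keep <- setdiff(seq_len(k), pair)
      str <- c(str[keep], merged)
      height <- c(height[keep], h)
    }
    paste0(str, ";")
  })
  ape::read.tree(text = nwk)
}

# Expected composition of one sample before counting noise.
# Inoculant fraction is imposed after the soft-max over the remaining
# features, so control samples carry exactly zero inoculant.
expected_composition <- function(soil, treatment, day, design, effects,
                                 directions) {
  feats <- default_feature_ids(design$n_features)
  ino <- effects$inoculant_feature_id
  idx_ino <- match(ino, feats)
  alpha <- effects$soil_baseline_concentration[[soil]][feats]
  logp <- log(alpha / sum(alpha))

  mag <- if (max(design$days) > 0) {
    effects$drift_scale * sqrt(day / max(design$days))
  } else 0
  inoculated <- identical(treatment, design$inoculated_label)
  dir <- if (inoculated) directions[[soil]]$drift_inoc else
    directions[[soil]]$drift
  logp <- logp + mag * dir
  if (inoculated) {
    logp <- logp + effects$treatment_shift[[soil]] * directions[[soil]]$shift
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)

  f <- 0
  if (inoculated && effects$inoculant_initial_fraction > 0) {
    f0 <- effects$inoculant_initial_fraction
    f1 <- effects$inoculant_residual_fraction[[soil]]
    d0 <- min(design$days); d1 <- max(design$days)
    f <- if (d1 == d0 || f0 == 0) f0 else if (f1 == 0 && day == d1) 0 else {
      # log-linear interpolation between the Day-0 spike and the residual
      exp(log(f0) + (log(max(f1, 1e-300)) - log(f0)) * (day - d0) / (d1 - d0))
    }
  }
  p[idx_ino] <- 0
  p <- p / sum(p) * (1 - f)
  p[idx_ino] <- f
  names(p) <- feats
  p
}

# Fixed per-soil unit directions in log-composition space, derived from the
# design seed: a drift direction, its rotated copy for inoculated samples,
# and a treatment-shift direction. The divergence angle is imposed on the
# *realised* composition displacements (what abundance-based distances
# see), not on the log-space directions: the soft-max map from log
# perturbations to relative-abundance changes re-correlates directions that
# are orthogonal in log space, so the mixing angle is solved numerically
# such that the expected Day-0 -> final-day displacement of inoculated
# samples makes the requested angle with the control displacement.
soil_directions <- function(design, effects) {
  p <- design$n_features
  feats <- default_feature_ids(p)
  with_seed(substream_seed(design$seed, "directions"), {
    out <- list()
    for (s in design$soils) {
      a <- effects$soil_baseline_concentration[[s]][feats]
      w <- a / sum(a)
      v1 <- stats::rnorm(p); v1 <- v1 / sqrt(sum(v1^2))
      v2 <- stats::rnorm(p); v2 <- v2 - sum(v2 * v1) * v1
      v2 <- v2 / sqrt(sum(v2^2))
      sh <- stats::rnorm(p); sh <- sh / sqrt(sum(sh^2))
      ang <- effects$divergence_angle[[s]]
      sc <- effects$drift_scale
      drift_inoc <- if (ang == 0 || sc == 0) {
        cos(ang) * v1 + sin(ang) * v2
      } else {
        disp <- function(v) {
          q <- w * exp(sc * v); q <- q / sum(q); q - w
        }
        m1 <- disp(v1)
        obj <- function(t) {
          m2 <- disp(cos(t) * v1 + sin(t) * v2)
          sum(m1 * m2) / sqrt(sum(m1^2) * sum(m2^2)) - cos(ang)
        }
        t_star <- tryCatch(stats::uniroot(obj, c(0, pi), tol = 1e-8)$root,
                           error = function(e) ang)
        cos(t_star) * v1 + sin(t_star) * v2
      }
      out[[s]] <- list(drift = v1, drift_inoc = drift_inoc, shift = sh)
    }
    out
  })
}

#' Simulate a microcosm count table
#'
#' Draws one sample per metadata row: the expected composition combines the
#' soil baseline, day-scaled drift, treatment shift and the imposed
#' inoculant fraction (see [effect_spec()]); counts are then drawn from a
#' Dirichlet-multinomial with the requested overdispersion, at a
#' Poisson-distributed library size centred on `library_size`.
#'
#' @param design a [design_spec()].
#' @param effects an [effect_spec()]; default `effect_spec(design)`.
#' @return Integer matrix (samples x features) with sample identifiers as
#'   row names and feature identifiers as column names. The matching
#'   metadata is attached as attribute `"metadata"` and also available via
#'   [generate_metadata()].
#' @export
#' @examples
#' d <- design_spec(n_features = 50, library_size = 1000)
#' tab <- generate_counts(d)
#' dim(tab)  # 90 x 50
generate_counts <- function(design, effects = effect_spec(design)) {
  stopifnot(inherits(design, "design_spec"), inherits(effects, "effect_spec"))
  md <- generate_metadata(design)
  feats <- default_feature_ids(design$n_features)
  if (!effects$inoculant_feature_id %in% feats) {
    stop("unknown inoculant feature: ", effects$inoculant_feature_id)
  }
  dirs <- soil_directions(design, effects)
  counts <- with_seed(substream_seed(design$seed, "counts"), {
    m <- matrix(0L, nrow(md), length(feats),
                dimnames = list(md$sample_id, feats))
    for (i in seq_len(nrow(md))) {
      pexp <- expected_composition(md$soil[i], md$treatment[i], md$day[i],
                                   design, effects, dirs)
      n_i <- stats::rpois(1L, design$library_size)
      if (n_i == 0L) next
      g <- stats::rgamma(length(pexp), shape = effects$overdispersion * pexp)
      if (sum(g) == 0) next
      m[i, ] <- stats::rmultinom(1L, n_i, g / sum(g))[, 1L]
    }
    m
  })
  attr(counts, "metadata") <- md
  counts
}

#' Drop features with low total counts
#'
#' Removes features whose summed count across all samples is strictly below
#' `threshold` (the rare-sequence filter applied to UMI tables, and the
#' minimum-feature-count pre-filter of the robust Aitchison analysis).
#' Sample rows and the order of the surviving features are unchanged.
#'
#' @param table samples x features count matrix.
#' @param threshold non-negative minimum total count a feature must reach.
#' @return The filtered count matrix (possibly with zero columns).
#' @export
apply_min_count_filter <- function(table, threshold) {
  stopifnot(is.matrix(table), threshold >= 0)
  keep <- colSums(table) >= threshold
  out <- table[, keep, drop = FALSE]
  md <- attr(table, "metadata")
  if (!is.null(md)) attr(out, "metadata") <- md
  out
}
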