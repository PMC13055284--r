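#' Default pipeline configuration
#'
#' A nested list mirroring the design/effect fields of the synthetic
#' generator plus the analysis parameters of every stage. Either the
#' `synthetic` block is used (default) or `input` paths to a count table,
#' metadata table and Newick tree are given.
#'
#' @param seed master seed for the whole run.
#' @param outdir output directory for artifacts.
#' @return A named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("microtraj_run_")) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    input = list(counts = NULL, metadata = NULL, tree = NULL),
    synthetic = list(
      soils = c("ANT", "AT", "G"),
      treatments = c("control", "inoculated"),
      replicates = 3L,
      days = c(0L, 14L, 28L, 57L, 249L),
      n_features = 500L,
      library_size = 1e5,
      inoculant_initial_fraction = 0.05,
      inoculant_residual_fraction = c(ANT = 0.0005, AT = 0.0017, G = 0.0033),
      overdispersion = 200,
      drift_scale = 16,
      treatment_shift = c(ANT = 0.8, AT = 0.8, G = 0.8),
      divergence_angle = c(ANT = 0.20, AT = 0.28, G = 1.25)),
    filter = list(min_total_count = 10L),
    distance = list(metrics = c("bray_curtis", "weighted_unifrac"),
                    unifrac_normalized = TRUE),
    embedding = list(
      methods = c("sammon", "rpca"),
      distance_for_sammon = "weighted_unifrac",
      dims = default_sweep_dims(),
      rpca_min_feature_count = 8L,
      nmds_n_starts = 20L,
      nmds_max_iter = 300L),
    trajectory = list(
      intervals = list(c(0L, 249L), c(0L, 14L), c(14L, 28L), c(28L, 57L),
                       c(57L, 249L))),
    diagnostics = list(k = 5L, m = 50L),
    inference = list(terms = c("soil", "day", "treatment"),
                     soil_term = "treatment", n_perm = 999L)),
    class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a `"pipeline_config"` (or compatible list).
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  # named atomic vectors (per-soil parameters) become YAML maps so their
  # names survive the round trip
  to_tree <- function(x) {
    if (is.list(x)) {
      lapply(x, to_tree)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(to_tree(unclass(config)), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

#' Validate a count table / metadata / tree trio
#'
#' Cross-checks sample identifier agreement between the count table and
#' metadata (fatal on mismatch), tree leaf coverage of nonzero features
#' (fatal) and of zero-count features (warning only), and completeness of
#' the metadata factor columns.
#'
#' @param table samples x features count matrix.
#' @param metadata sample metadata data.frame.
#' @param tree optional `"phylo"` tree.
#' @return list with character vectors `fatal` and `warnings`.
#' @export
validate_inputs <- function(table, metadata, tree = NULL) {
  fatal <- character(0); warn <- character(0)
  miss_md <- setdiff(rownames(table), metadata$sample_id)
  if (length(miss_md)) {
    fatal <- c(fatal, paste0("samples missing from metadata: ",
                             paste(miss_md, collapse = ", ")))
  }
  extra_md <- setdiff(metadata$sample_id, rownames(table))
  if (length(extra_md)) {
    warn <- c(warn, paste0("metadata rows without counts: ",
                           paste(extra_md, collapse = ", ")))
  }
  need <- c("sample_id", "soil", "treatment", "day", "replicate")
  lack <- setdiff(need, names(metadata))
  if (length(lack)) {
    fatal <- c(fatal, paste0("metadata lacks column(s): ",
                             paste(lack, collapse = ", ")))
  }
  if (!is.null(tree)) {
    nz <- colnames(table)[colSums(table) > 0]
    z <- setdiff(colnames(table), nz)
    miss_nz <- setdiff(nz, tree$tip.label)
    if (length(miss_nz)) {
      fatal <- c(fatal, paste0("nonzero features absent from tree: ",
                               paste(miss_nz, collapse = ", ")))
    }
    miss_z <- setdiff(z, tree$tip.label)
    if (length(miss_z)) {
      warn <- c(warn, paste0("zero-count features absent from tree: ",
                             paste(miss_z, collapse = ", ")))
    }
  }
  list(fatal = fatal, warnings = warn)
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: obtain data (synthetic generation or file
#' input), low-count feature filtering, distance computation (Bray-Curtis
#' and weighted UniFrac), embedding sweeps (Sammon mapping of the chosen
#' distance and robust Aitchison PCA of the counts, across the configured
#' dimensionalities), trajectory geometry, dimensionality diagnostics,
#' alpha diversity, global and per-soil PERMANOVA on each distance matrix,
#' and dimension-swept PERMANOVA on distances reconstructed from the RPCA
#' embeddings. Every numeric artifact is written as TSV under the output
#' directory and checksummed into the returned manifest; embedding
#' dimensionalities at which a method fails are recorded as skips.
#'
#' @param config a [pipeline_config()].
#' @return The run manifest: a list with `parameters`, `artifacts`
#'   (file path and md5 per artifact), `embeddings` (per method: embedded
#'   and skipped dimensions), and `warnings`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  cfg <- config
  if (is.null(cfg$seed)) stop("config must set a seed")
  known <- c("pcoa", "sammon", "nmds", "rpca")
  bad <- setdiff(cfg$embedding$methods, known)
  if (length(bad)) {
    stop("unknown embedding method(s): ", paste(bad, collapse = ", "))
  }
  dims <- unlist(cfg$embedding$dims)
  if (!length(dims) || is.unsorted(dims, strictly = TRUE) || any(dims < 1)) {
    stop("embedding$dims must be a strictly increasing list of positive integers")
  }
  for (p in Filter(Negate(is.null), unlist(cfg$input))) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = unclass(cfg), artifacts = list(),
                   embeddings = list(), warnings = character(0))
  art <- function(name, path) {
    manifest$artifacts[[name]] <<- list(
      path = path, md5 = unname(tools::md5sum(path)))
  }
  stage <- "input"
  res <- tryCatch({
    if (!is.null(cfg$input$counts)) {
      table <- read_count_table(cfg$input$counts)
      metadata <- read_metadata(cfg$input$metadata)
      tree <- if (!is.null(cfg$input$tree)) read_tree_newick(cfg$input$tree)
              else NULL
    } else {
      sy <- cfg$synthetic
      design <- design_spec(soils = sy$soils, treatments = sy$treatments,
                            replicates = sy$replicates, days = sy$days,
                            n_features = sy$n_features,
                            library_size = sy$library_size, seed = cfg$seed)
      effects <- effect_spec(
        design, drift_scale = sy$drift_scale,
        treatment_shift = unlist(sy$treatment_shift),
        divergence_angle = unlist(sy$divergence_angle),
        inoculant_initial_fraction = sy$inoculant_initial_fraction,
        inoculant_residual_fraction = unlist(sy$inoculant_residual_fraction),
        overdispersion = sy$overdispersion)
      table <- generate_counts(design, effects)
      metadata <- generate_metadata(design)
      tree <- generate_tree(design$n_features, seed = cfg$seed)
    }
    rep <- validate_inputs(table, metadata, tree)
    if (length(rep$fatal)) {
      stop("input validation failed: ", paste(rep$fatal, collapse = "; "))
    }
    manifest$warnings <- c(manifest$warnings, rep$warnings)
    write_count_table(table, file.path(cfg$outdir, "counts.tsv"))
    art("counts", file.path(cfg$outdir, "counts.tsv"))
    write_metadata(metadata, file.path(cfg$outdir, "metadata.tsv"))
    art("metadata", file.path(cfg$outdir, "metadata.tsv"))
    if (!is.null(tree)) {
      write_tree_newick(tree, file.path(cfg$outdir, "tree.nwk"))
      art("tree", file.path(cfg$outdir, "tree.nwk"))
    }

    stage <- "filter"
    table <- apply_min_count_filter(table, cfg$filter$min_total_count)

    stage <- "distance"
    distances <- list()
    if ("bray_curtis" %in% cfg$distance$metrics) {
      distances$bray_curtis <- bray_curtis(table)
    }
    if ("weighted_unifrac" %in% cfg$distance$metrics) {
      if (is.null(tree)) stop("weighted UniFrac requested but no tree given")
      distances$weighted_unifrac <-
        weighted_unifrac(table, tree,
                         normalized = isTRUE(cfg$distance$unifrac_normalized))
    }
    for (nm in names(distances)) {
      p <- file.path(cfg$outdir, paste0("distance_", nm, ".tsv"))
      write_distance_matrix(distances[[nm]], p)
      art(paste0("distance_", nm), p)
    }

    stage <- "embedding"
    sweeps <- list()
    dims <- unlist(cfg$embedding$dims)
    for (method in cfg$embedding$methods) {
      src <- switch(method,
                    rpca = table,
                    distances[[cfg$embedding$distance_for_sammon]])
      extra <- switch(method,
                      rpca = list(min_feature_count =
                                    cfg$embedding$rpca_min_feature_count),
                      nmds = list(n_starts = cfg$embedding$nmds_n_starts,
                                  max_iter = cfg$embedding$nmds_max_iter),
                      list())
      sw <- do.call(sweep_embeddings,
                    c(list(source = src, method = method, dims = dims,
                           seed = cfg$seed), extra))
      sweeps[[method]] <- sw
      manifest$embeddings[[method]] <- list(
        embedded = as.integer(sub("^d", "", names(sw$embeddings))),
        skipped = sw$skipped)
      for (nm in names(sw$embeddings)) {
        p <- file.path(cfg$outdir,
                       paste0("embedding_", method, "_", nm, ".tsv"))
        write_embedding(sw$embeddings[[nm]], p)
        art(paste0("embedding_", method, "_", nm), p)
      }
    }

    geo_method <- setdiff(cfg$embedding$methods, "rpca")[1L]
    if (!is.na(geo_method) && length(sweeps[[geo_method]]$embeddings)) {
      stage <- "trajectory"
      traj <- sweep_trajectory_metrics(
        sweeps[[geo_method]], metadata,
        intervals = cfg$trajectory$intervals)
      p <- file.path(cfg$outdir, "trajectory_metrics.tsv")
      utils::write.table(traj, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      art("trajectory_metrics", p)

      stage <- "diagnostics"
      diag_tab <- sweep_diagnostics(sweeps[[geo_method]], metadata,
                                    k = cfg$diagnostics$k,
                                    m = cfg$diagnostics$m, seed = cfg$seed)
      p <- file.path(cfg$outdir, "dimension_diagnostics.tsv")
      utils::write.table(diag_tab, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      art("dimension_diagnostics", p)
    }

    stage <- "alpha_diversity"
    alpha <- alpha_diversity(table)
    p <- file.path(cfg$outdir, "alpha_diversity.tsv")
    utils::write.table(alpha, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    art("alpha_diversity", p)

    stage <- "permanova"
    perm_rows <- list()
    for (nm in names(distances)) {
      gl <- permanova(distances[[nm]], metadata,
                      terms = cfg$inference$terms,
                      n_perm = cfg$inference$n_perm,
                      seed = substream_seed(cfg$seed, paste0("perm_", nm)))
      keep <- gl$term != "Residual"
      perm_rows[[length(perm_rows) + 1L]] <- data.frame(
        metric = nm, scope = "global", term = gl$term[keep],
        R2 = gl$R2[keep], F = gl$F[keep], p_value = gl$p_value[keep])
      for (soil in unique(metadata$soil)) {
        sel <- intersect(rownames(distances[[nm]]),
                         metadata$sample_id[metadata$soil == soil])
        sw <- permanova(distances[[nm]][sel, sel, drop = FALSE],
                        metadata[metadata$sample_id %in% sel, , drop = FALSE],
                        terms = cfg$inference$soil_term,
                        n_perm = cfg$inference$n_perm,
                        seed = substream_seed(cfg$seed,
                                              paste0("perm_", nm, "_", soil)))
        keep <- sw$term != "Residual"
        perm_rows[[length(perm_rows) + 1L]] <- data.frame(
          metric = nm, scope = soil, term = sw$term[keep],
          R2 = sw$R2[keep], F = sw$F[keep], p_value = sw$p_value[keep])
      }
    }
    perm_tab <- do.call(rbind, perm_rows)
    p <- file.path(cfg$outdir, "permanova.tsv")
    utils::write.table(perm_tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    art("permanova", p)

    if ("rpca" %in% names(sweeps) && length(sweeps$rpca$embeddings)) {
      stage <- "permanova_sweep"
      psw <- permanova_sweep(sweeps$rpca, metadata,
                             terms = cfg$inference$terms,
                             soil_term = cfg$inference$soil_term,
                             n_perm = cfg$inference$n_perm,
                             seed = cfg$seed)
      p <- file.path(cfg$outdir, "permanova_dimension_sweep.tsv")
      utils::write.table(psw, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      art("permanova_dimension_sweep", p)
    }
    manifest
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  p <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(
    list(parameters = res$parameters,
         artifacts = res$artifacts,
         embeddings = lapply(res$embeddings, function(x) {
           list(embedded = x$embedded, skipped = x$skipped)
         }),
         warnings = res$warnings),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  res$manifest_path <- p
  invisible(res)
}
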