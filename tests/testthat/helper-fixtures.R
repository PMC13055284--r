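# Small fixtures shared across test files; everything is generated in code.

tiny_design <- function(seed = 7L, n_features = 40L, library_size = 2000,
                        days = c(0L, 14L, 28L, 57L, 249L), replicates = 3L) {
  design_spec(n_features = n_features, library_size = library_size,
              days = days, replicates = replicates, seed = seed)
}

# metadata + coordinates for hand-constructed trajectory tests
manual_embedding <- function(coords, method = "manual") {
  new_embedding(coords, method)
}

# an embedding whose coordinates are given exactly (bypassing the centring/
# sign canonicalisation, for tests that need verbatim coordinates)
raw_embedding <- function(coords, method = "manual") {
  structure(list(points = coords, method = method, dimension = ncol(coords),
                 diagnostics = list()),
            class = "embedding")
}

# metadata data.frame for an arbitrary coordinate matrix
simple_metadata <- function(ids, soil = "S", treatment = "control",
                            day = 0L, replicate = 1L) {
  data.frame(sample_id = ids, soil = soil, treatment = treatment,
             day = day, replicate = replicate)
}
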