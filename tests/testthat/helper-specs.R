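# Shared phantom geometries, sized for test speed.

# Small full-pipeline phantom (works with the default sigma = 2 pipeline).
small_phantom_spec <- function(radial_density = "uniform-disk", seed = 1) {
  phantom_spec(stack_shape = c(9L, 192L, 192L), cell_radius = 4,
               nucleus_radius = 0.4, n_mito = 12,
               mito_length_range = c(0.5, 1.2), mito_radius = 0.22,
               radial_density = radial_density, seed = seed)
}

# Radial-law phantom: compact mitochondria in a large cell, so the pooled
# normalized pixel distances track the placement family's CDF closely.
lawcheck_phantom_spec <- function(seed = 1) {
  phantom_spec(stack_shape = c(11L, 466L, 466L), cell_radius = 12,
               nucleus_radius = 0.4, n_mito = 25,
               mito_length_range = c(0.1, 0.3), mito_radius = 0.28,
               seed = seed)
}
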