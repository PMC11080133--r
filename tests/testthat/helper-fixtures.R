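# shared fixtures, all built in code

default_grid <- function() potential_grid()

# design -> concentration table on the bundled analyte ranges
design_conc <- function() {
  specs <- default_analyte_specs()
  map_levels_to_concentrations(brereton_design(5, 3),
                               lapply(specs, function(s) s$linear_range))
}

# small deterministic voltammogram set
tiny_set <- function(n = 3, seed = 42) {
  g <- potential_grid(0, 0.1, 0.01)   # 11 points
  set.seed(seed)
  voltammogram_set(g, matrix(rnorm(n * g$n_points), n))
}

# synthetic set with chosen artifacts on the full bundled system
synth_set <- function(artifacts, conc = design_conc(),
                      specs = default_analyte_specs()) {
  generate_mixture_set(conc, specs, artifacts, potential_grid())
}
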