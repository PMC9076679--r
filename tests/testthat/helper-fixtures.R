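# Shared simulated fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Small regional fleet (recovery-style configuration, scaled down).
small_regional_sim <- function() {
  cached("regional", function() {
    sim_fleet(sim_config(migratory = FALSE, n_animals = 8L, n_mothers = 4L,
                         n_fixes = 80L), seed = 401)
  })
}

# Small migratory fleet (full pipeline shape, scaled down).
small_migratory_sim <- function() {
  cached("migratory", function() {
    sim_fleet(sim_config(n_animals = 6L, n_mothers = 3L, n_period1 = 2L,
                         n_fixes = 260L, gap_mean_h = 3), seed = 402)
  })
}

small_fields <- function() {
  cached("fields", function() {
    gen_covariate_fields(sim_config(migratory = FALSE), seed = 401)
  })
}
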