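# Shared fixtures. Everything is generated in code; the heavier pipeline
# runs are cached per session so that several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# A small, fully controlled cohort: three subtypes, four planted modules
# (A/B anti-correlated between X and Y, C specific to Z, D shared X/Z),
# plus background. Distinct module profiles make recovery identifiable.
small_spec <- function(seed = 42L, sigma_act = 0.15, sigma_eps = 0.5,
                       background_genes = 200L, counts = c(X = 15L, Y = 15L,
                                                           Z = 10L)) {
  act <- matrix(0, 3, 4,
                dimnames = list(c("X", "Y", "Z"), c("A", "B", "C", "D")))
  act["X", ] <- c(1, -1, 0, 0.5)
  act["Y", ] <- c(-1, 1, 0, 0)
  act["Z", ] <- c(0, 0, 1, 0.5)
  cohort_spec(strata_counts = counts, activation = act,
              module_sizes = c(A = 40L, B = 40L, C = 30L, D = 30L),
              sigma_act = sigma_act, sigma_eps = sigma_eps,
              background_genes = background_genes, seed = seed)
}

small_cohort <- function() cached("small_cohort", generate_cohort(small_spec()))

# small cohort taken through preprocessing and a 10x10 SOM
small_pipeline <- function() cached("small_pipeline", {
  ch <- small_cohort()
  cfg <- pipeline_config(grid_rows = 10L, grid_cols = 10L, epochs = 10L,
                         spot_quantile = 0.80, seed = 7L)
  pl <- som_pipeline(ch$expression, config = cfg)
  pl$truth <- ch$truth
  pl$match <- match_spots_to_modules(pl$spots, ch$truth)
  pl
})

# Default-cohort pipeline runs at the package defaults (the benchmark
# conditions); cached because several acceptance criteria share them.
default_run <- function(seed) cached(paste0("default_run_", seed),
                                     run_default_pipeline(seed = seed))

# write a small TSV expression fixture on the fly
write_tsv_fixture <- function(values, path) {
  E <- expression_matrix(values)
  write_expression(E, path)
  path
}
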