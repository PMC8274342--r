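# Shared fixtures, built once per test run.  Meshes are deterministic, so
# caching them is purely a speed concern.

.fixtures <- new.env(parent = emptyenv())

fixture_mesh <- function(subdivisions = 2) {
  key <- paste0("mesh", subdivisions)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- cortical_mesh(subdivisions = subdivisions)
  .fixtures[[key]]
}

fixture_cohort <- function(key = "small", ...) {
  k <- paste0("cohort_", key)
  if (is.null(.fixtures[[k]])) {
    args <- list(...)
    cfg <- do.call(cohort_config, args$config %||% list(
      n_yhc = 2, n_ehc = 8, n_amci = 5, n_add = 5, seed = 42))
    .fixtures[[k]] <- generate_cohort(cfg, args$mesh %||% fixture_mesh(2))
  }
  .fixtures[[k]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scale a surface map and strip attributes
scale1 <- function(x, spec, mesh) as.numeric(scale_image(x, spec, mesh = mesh))
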