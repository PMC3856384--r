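# Shared, lazily computed phantom pipeline runs.  The full-size human run
# takes tens of seconds, so test files reuse one cached result instead of
# recomputing it.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

default_human_phantom <- function(seed = 1, ...) {
  cached(paste0("hph_", seed, "_", paste(c(...), collapse = "_")),
         make_phantom(human_phantom_spec(seed = seed, ...)))
}

default_human_run <- function(seed = 1) {
  cached(paste0("hrun_", seed), {
    ph <- default_human_phantom(seed)
    extract_brain_human(ph$volume, keep_trace = TRUE)
  })
}

marrow_run <- function(seed = 1) {
  cached(paste0("mrun_", seed), {
    ph <- default_human_phantom(seed, marrow_patches = 6)
    extract_brain_human(ph$volume, keep_trace = TRUE)
  })
}

default_macaque_phantom <- function(seed = 1, ...) {
  cached(paste0("mph_", seed, "_", paste(c(...), collapse = "_")),
         make_phantom(macaque_phantom_spec(seed = seed, ...)))
}

default_macaque_run <- function(seed = 1, bias_amplitude = 0) {
  cached(paste0("mqrun_", seed, "_", bias_amplitude), {
    ph <- default_macaque_phantom(seed, bias_amplitude = bias_amplitude)
    extract_brain_macaque(ph$volume, bias_correct = bias_amplitude > 0,
                          keep_trace = TRUE)
  })
}
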