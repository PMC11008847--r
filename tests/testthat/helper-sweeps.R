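# Densification sweeps are the expensive shared inputs of several layer-
# level checks; compute each at most once per test run.
.sweep_cache <- new.env(parent = emptyenv())

cached_sweep <- function(key, fun) {
  if (is.null(.sweep_cache[[key]])) .sweep_cache[[key]] <- fun()
  .sweep_cache[[key]]
}

standard_sweep <- function() {
  cached_sweep("standard", function() densification_sweep(seed = 1L))
}

weak_cc_sweep <- function() {
  cached_sweep("weak_cc", function()
    densification_sweep(params = model_params(gamma_cc = 1e-5), seed = 1L))
}
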