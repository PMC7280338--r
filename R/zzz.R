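.onLoad <- function(libname, pkgname) {
  register_classifier("slow_fast", function(recording, params) {
    classify_slow_fast(
      recording,
      velocity_threshold_dps = params$velocity_threshold_dps %||% 100,
      min_fast_ms = params$min_fast_ms %||% 10,
      min_slow_ms = params$min_slow_ms %||% 40)
  })
  invisible()
}
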