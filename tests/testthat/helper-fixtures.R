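# Small shared fixtures, built in code.

tiny_model_config <- function(...) {
  model_config(input_samples = 48L, n_blocks = 4L, blocks_per_stage = 2L,
               initial_depth = 4L, n_heads = 2L, classifier_hidden = 8L, ...)
}

# A config with full-length 625-sample input but a light encoder, for
# tests that exercise record-shaped data without full-model cost.
small_model_config <- function() {
  model_config(input_samples = 625L, n_blocks = 4L, blocks_per_stage = 2L,
               initial_depth = 8L, n_heads = 4L, classifier_hidden = 16L)
}

random_segments <- function(cfg, B, sd = 0.5) {
  array(stats::rnorm(cfg$input_samples * 12 * B, sd = sd),
        c(cfg$input_samples, 12L, B))
}

# A consistent set of limb leads derived from random I and II.
random_limb_leads <- function(n = 20) {
  i <- stats::rnorm(n)
  ii <- stats::rnorm(n)
  list(I = i, II = ii, III = ii - i, aVR = -(i + ii) / 2,
       aVL = i - ii / 2, aVF = ii - i / 2)
}

quiet_synth_config <- function(...) {
  synth_config(noise_sd = 0, ...)
}
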