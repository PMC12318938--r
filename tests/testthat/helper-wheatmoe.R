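# Shared test fixtures and oracles, built in code.

# tiny model configuration for fast structural and gradient tests
tiny_config <- function(...) {
  model_config("desk", d = 8, n_heads = 2, n_enc_layers = 1, lstm_layers = 2,
               gate_hidden = 12, fusion_dims = c(10, 6), ff_dim = 16, ...)
}

fixture_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture(0)
    cache
  }
})

# central finite-difference gradient of a scalar function
numeric_grad <- function(f, x, eps = 1e-5) {
  (f(x + eps) - f(x - eps)) / (2 * eps)
}

rel_err <- function(a, b) abs(a - b) / pmax(1e-6, abs(a) + abs(b))

random_sample_array <- function(b, t = 10, f = 10, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(b * t * f), c(b, t, f))
}
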