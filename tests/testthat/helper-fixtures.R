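# shared fixtures, built once per test run

# straight unbranched chain along +x with given segment lengths
chain_morphology <- function(seg_lengths, radius = 0.5, soma_radius = NULL) {
  n <- length(seg_lengths) + 1L
  if (is.null(soma_radius)) soma_radius <- radius
  sac_morphology(data.frame(
    id = seq_len(n),
    parent_id = c(-1L, seq_len(n - 1L)),
    x = c(0, cumsum(seg_lengths)), y = 0, z = 0,
    radius = c(soma_radius, rep(radius, n - 1L)),
    kind = c("soma", rep("dendrite", n - 1L))))
}

soma_only_morphology <- function(radius = 4) {
  sac_morphology(data.frame(id = 1L, parent_id = -1L, x = 0, y = 0, z = 0,
                            radius = radius, kind = "soma"))
}

# memoised default SAC model (the expensive shared fixture)
.fixture_env <- new.env(parent = emptyenv())

default_sac_model <- function(dx_max = 2) {
  key <- paste0("model_dx", dx_max)
  if (is.null(.fixture_env[[key]])) {
    if (is.null(.fixture_env$morph)) {
      .fixture_env$morph <- generate_sac_morphology(seed = 1)
    }
    .fixture_env[[key]] <- discretize(.fixture_env$morph, passive_params(),
                                      dx_max = dx_max)
  }
  .fixture_env[[key]]
}

default_sac_morphology <- function() {
  if (is.null(.fixture_env$morph)) {
    .fixture_env$morph <- generate_sac_morphology(seed = 1)
  }
  .fixture_env$morph
}
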