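# Shared trained fixtures, built once per test run and memoised.  All sizes
# are the package's desk-scale study conditions: 32x32 phantoms, latent
# dimension 64, narrow networks.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env, inherits = FALSE)
}

fixture_phantoms <- function() {
  fixture("phantoms64", function()
    generate_phantom(phantom_spec(resolution = 32, seed = 1), 64))
}

# one quickly trained model for smoke-level inversion tests
fixture_tiny_gan <- function() {
  fixture("tiny_gan", function() {
    cfg <- gan_config(resolution = 32, latent_dim = 64, steps = 300,
                      base_channels = 4, channel_cap = 64, seed = 7)
    train_gan(fixture_phantoms(), cfg)
  })
}

# the 3-model ensemble of the desk-scale study (2000 steps each) plus one
# trained encoder for model 1; reused by the acceptance suite
fixture_ensemble <- function() {
  fixture("ensemble", function() {
    ds <- fixture_phantoms()
    lapply(0:2, function(k) {
      cfg <- gan_config(resolution = 32, latent_dim = 64, steps = 2000,
                        base_channels = 4, channel_cap = 64, seed = 1 + k)
      train_gan(ds, cfg)
    })
  })
}

fixture_encoder <- function() {
  fixture("encoder", function() {
    cfg <- encoder_config(steps = 1500, base_channels = 8, channel_cap = 64,
                          seed = 1)
    train_encoder(fixture_phantoms(), fixture_ensemble()[[1]], cfg)
  })
}

fixture_restore_cfg <- function(steps = 200) {
  restoration_config(steps = steps, lr = 0.05)
}
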