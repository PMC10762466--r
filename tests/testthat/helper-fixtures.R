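# Shared fixtures.  Heavier artefacts (pretrained SSM, the trained paradigm
# benchmark) are built once per test session and memoised in this
# environment so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tiny_dataset <- function(n = 4, seed = 42) {
  fixture(paste0("ds_", n, "_", seed), function() make_dataset(n, seed = seed))
}

# small pretrained segmentation module shared across test files
fixture_ssm <- function() {
  fixture("ssm_pre", function() {
    train <- make_dataset(20, seed = 11)
    pretrain_ssm(train, fsl_config(seed = 3, lr = 3e-3, batch = 2,
                                   pretrain_steps = 250))
  })
}

# access an internal (non-exported) function of the package
internal <- function(name) {
  utils::getFromNamespace(name, "fslmri")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

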