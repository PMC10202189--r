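# Shared fixtures, all generated in code. Expensive objects are memoized in
# this environment so one test run builds them once.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a small cultivation: 45 days, enough for L = 3 windows
tiny_scenario <- function(seed = 7L)
  cultivation_scenario(n_days = 45L, seed = seed, id = paste0("tiny", seed))

tiny_env <- function() memo("tiny_env", function()
  generate_environment(tiny_scenario()))

tiny_truth <- function() memo("tiny_truth", function()
  simulate_reference_growth(tiny_env(), scenario = tiny_scenario()))

tiny_labels <- function() memo("tiny_labels", function() {
  obs <- sample_destructive_observations(tiny_truth(), n_dates = 4L,
                                         cv = 0.05, seed = 11L)
  interpolate_growth_daily(obs)
})

tiny_windows <- function() memo("tiny_windows", function()
  make_training_windows(list(list(env = tiny_env(), labels = tiny_labels(),
                                  id = "tiny")),
                        memory_length = 3L, split = 0.75, seed = 5L))

# micro architecture used wherever a constructed (untrained) model suffices
micro_config <- function(L = 3L, ...)
  attncrop_config(memory_length = L, d_model = 16L, n_heads = 2L,
                  n_encoder_blocks = 1L, n_decoder_blocks = 1L,
                  kernels = c(1L, 3L), ff_width = 24L, seed = 3L, ...)

# an untrained model wrapper around freshly initialized parameters
micro_model <- function(cfg = micro_config(), scaler = NULL) {
  ns <- asNamespace("attncrop")
  if (is.null(scaler))
    scaler <- suppressWarnings(fit_scaler(tiny_windows()$train))
  structure(list(params = ns$init_params(cfg),
                 norm = ns$init_norm_state(cfg),
                 scaler = scaler, config = cfg, trace = NULL,
                 best_epoch = 0L, call = NULL),
            class = "attncrop")
}

# one trained tiny model, reused by simulation/evaluation tests
tiny_fit <- function() memo("tiny_fit", function()
  suppressWarnings(attncrop(tiny_windows(), micro_config(), epochs = 4L,
                            seed = 3L)))

# random standardized batch for forward/backward structural tests
random_batch <- function(cfg, B = 2L, seed = 42L) {
  ns <- asNamespace("attncrop")
  L <- cfg$memory_length
  nf <- length(cfg$factor_names)
  with_seed_test(seed, list(
    X = matrix(stats::rnorm(B * 24L * L * cfg$n_features), B * 24L * L,
               cfg$n_features),
    P = matrix(stats::rnorm(B * L * nf), B * L, nf),
    target = matrix(stats::rnorm(B * L * nf), B * L, nf), B = B))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
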