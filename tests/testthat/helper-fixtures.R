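# Shared fixtures, built once per test run and memoised: the expensive
# pieces (trained networks, multi-subject datasets) are reused across
# test files.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# Study conditions for the 10-class single-subject recognition experiment:
# high separation, low sensor noise.
fx_spec10 <- function() synthetic_spec(n_classes = 10, n_subjects = 3,
                                       n_sessions = 10, separation = 3,
                                       noise_sd = 0.05, seed = 11)

# Preprocessed TD4 features of subject 1.
fx_fs10 <- function() memo("fs10", {
  ds <- preprocess_dataset(generate_dataset(fx_spec10(), subjects = 1))
  extract_features(ds, "TD4")
})

fx_split10 <- function() memo("split10",
  split_dataset(fx_fs10(), train_control(seed = 7)))

# PICNN trained on the 80% split (the criterion allows up to 30 epochs).
fx_net10 <- function() memo("net10", {
  ctl <- train_control(epochs = 30, batch_size = 16, seed = 7)
  picnn(fx_split10()$train, control = ctl)
})

# Pretraining pool: subjects 1-2; new subject 3 with strongly shifted
# channel gains (domain shift).
fx_pretrained <- function() memo("pretrained", {
  ds <- preprocess_dataset(generate_dataset(fx_spec10(), subjects = 1:2))
  fs <- extract_features(ds, "TD4")
  picnn(fs, control = train_control(epochs = 15, batch_size = 16, seed = 7))
})

fx_newsubj <- function() memo("newsubj", {
  ds <- preprocess_dataset(generate_dataset(fx_spec10(), subjects = 3,
                                            gain_shift = 2.5))
  extract_features(ds, "TD4")
})

# A deliberately small 1-D model spec for cheap structural/training tests.
fx_tiny_spec <- function(n_classes = 2, n_channels = 2,
                         input_shape = c(32, 2)) {
  model_spec(n_channels = n_channels, n_classes = n_classes,
             input_shape = input_shape, dimensionality = "1d",
             inception = inception_spec(maps_per_kernel = 4,
                                        reduction_width = 4),
             conv_widths = c(8, 8, 12, 12, 16, 16))
}

# Linearly separable 1-D feature set: two classes with shifted means.
fx_separable_features <- function(n_per_class = 20, seed = 5) {
  with_seed <- semgssr:::with_seed
  with_seed(seed, {
    n <- 2 * n_per_class
    x <- array(rnorm(n * 2 * 32 * 2, sd = 0.3), c(n, 2, 32, 2))
    labels <- rep(0:1, each = n_per_class)
    x[labels == 1, , 10:20, ] <- x[labels == 1, , 10:20, ] + 2
    structure(list(x = x, labels = labels, subjects = rep(1L, n),
                   sessions = rep(1L, n), method = "TD4", n_classes = 2L),
              class = "feature_set")
  })
}

expect_simplex <- function(p, tol = 1e-6) {
  expect_true(all(p >= -tol))
  expect_true(all(abs(rowSums(p) - 1) < tol))
}
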