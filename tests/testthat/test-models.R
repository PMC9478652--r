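# Architectures: structural facts, simplex outputs, training behavior.

test_that("inception module concatenates 3 x 32 = 96 maps and pools", {
  mod <- build_inception_module(inception_spec(), c(36, 36), in_c = 1,
                                mode = "2d")
  x <- array(rnorm(2 * 36 * 36), c(2, 36, 36, 1))
  out <- semgssr:::nn_forward(mod, x)
  expect_identical(dim(out), c(2L, 18L, 18L, 96L))

  thin <- build_inception_module(inception_spec(maps_per_kernel = 1,
                                                reduction_width = 1),
                                 c(36, 36), 1, "2d")
  expect_identical(dim(semgssr:::nn_forward(thin, x))[4], 3L)

  expect_error(build_inception_module(inception_spec(), c(4, 4), 1, "2d"),
               "smaller than the largest kernel")
})

test_that("default PICNN audits to the printed architecture facts", {
  net <- memo("default_picnn", build_picnn(model_spec()))
  au <- model_audit(net)
  expect_identical(au$n_inception_modules, 6L)
  expect_identical(au$maps_per_module, 96L)
  expect_identical(au$concat_maps, 576L)
  expect_identical(au$n_block_conv, 6L)
  expect_identical(au$n_block_pool, 4L)
  expect_identical(au$n_global_pool, 1L)
  expect_identical(au$head_width, 101L)
})

test_that("network outputs are probability-simplex rows", {
  net <- build_picnn(fx_tiny_spec())
  x <- array(rnorm(3 * 2 * 32 * 2), c(3, 2, 32, 2))
  p <- predict(net, x, type = "prob")
  expect_simplex(p)
  # wrong channel count errors
  bad <- array(rnorm(3 * 4 * 32 * 2), c(3, 4, 32, 2))
  expect_error(predict(net, bad), "channels")
})

test_that("VGG baseline halves widths and shrinks the parameter count", {
  spec <- model_spec(n_channels = 2, n_classes = 5, input_shape = c(36, 36),
                     dimensionality = "2d")
  half <- build_cnn_baseline(spec, width_scale = 0.5)
  full <- build_cnn_baseline(spec, width_scale = 1)
  expect_lt(count_params(half), count_params(full))
  expect_identical(model_audit(half)$head_width, 5L)
  x <- array(rnorm(2 * 2 * 36 * 36), c(2, 2, 36, 36))
  expect_simplex(predict(half, x, type = "prob"))
})

test_that("single-trunk inception baseline concatenates channels first", {
  spec <- model_spec(n_channels = 6, n_classes = 7, input_shape = c(36, 36),
                     dimensionality = "2d",
                     conv_widths = c(8, 8, 12, 12, 16, 16))
  net <- build_inception_baseline(spec)
  # first conv consumes all 6 input planes at once
  convs <- Filter(function(e) e$kind == "conv",
                  semgssr:::nn_collect(net$graph))
  expect_equal(convs[[1]]$in_c, 6)
  au <- model_audit(net)
  expect_identical(au$n_inception_modules, 1L)
  expect_identical(au$maps_per_module, 96L)
  expect_identical(au$head_width, 7L)
  x <- array(rnorm(2 * 6 * 36 * 36), c(2, 6, 36, 36))
  expect_simplex(predict(net, x, type = "prob"))
})

test_that("split_dataset shuffles and rounds the 80/20 split half-up", {
  fake_fs <- function(n) structure(
    list(x = array(seq_len(n * 2 * 8 * 2), c(n, 2, 8, 2)),
         labels = rep_len(0:1, n), subjects = rep(1L, n),
         sessions = rep(1L, n), method = "TD4", n_classes = 2L),
    class = "feature_set")
  sp100 <- split_dataset(fake_fs(100), train_control(seed = 1))
  expect_identical(dim(sp100$train$x)[1], 80L)
  expect_identical(dim(sp100$test$x)[1], 20L)
  sp101 <- split_dataset(fake_fs(101), train_control(seed = 1))
  expect_identical(dim(sp101$train$x)[1], 81L)
  expect_identical(dim(sp101$test$x)[1], 20L)
  # union of splits is the original multiset of epochs
  key <- function(fs) sort(apply(fs$x, 1, function(a) sum(a * 1.0)))
  expect_equal(sort(c(key(sp101$train), key(sp101$test))),
               key(fake_fs(101)))
})

test_that("training learns a separable 2-class problem and is deterministic", {
  fs <- fx_separable_features()
  ctl <- train_control(epochs = 50, batch_size = 8, seed = 2,
                       validation_split = 0)
  set.seed(ctl$seed)
  net <- build_picnn(fx_tiny_spec())
  net <- train_net(net, fs, control = ctl)
  # inference-mode accuracy on the (separable) training data
  expect_gte(mean(predict(net, fs, type = "class") == fs$labels), 0.95)

  # identical seed -> identical final loss and weights
  set.seed(ctl$seed)
  net2 <- train_net(build_picnn(fx_tiny_spec()), fs, control = ctl)
  expect_identical(tail(net$history$loss, 1), tail(net2$history$loss, 1))
  expect_identical(semgssr:::nn_flatten_params(net$graph),
                   semgssr:::nn_flatten_params(net2$graph))

  # zero learning rate leaves all trainable parameters untouched
  set.seed(3)
  frozen <- build_picnn(fx_tiny_spec())
  before <- semgssr:::nn_flatten_params(frozen$graph)
  frozen <- train_net(frozen, fs,
                      control = train_control(epochs = 1, lr = 0, seed = 3,
                                              validation_split = 0))
  expect_identical(semgssr:::nn_flatten_params(frozen$graph), before)

  expect_error(train_net(build_picnn(fx_tiny_spec()),
                         feature_subset_empty <- structure(
                           list(x = array(0, c(0, 2, 32, 2)),
                                labels = integer(0), subjects = integer(0),
                                sessions = integer(0), method = "TD4",
                                n_classes = 2L), class = "feature_set"),
                         control = ctl),
               "empty training set")
})

test_that("inference is deterministic and batch-order equivariant", {
  fs <- fx_separable_features()
  net <- train_net(build_picnn(fx_tiny_spec()), fs,
                   control = train_control(epochs = 2, seed = 4,
                                           validation_split = 0))
  p1 <- predict(net, fs, type = "prob")
  p2 <- predict(net, fs, type = "prob")
  expect_identical(p1, p2)  # dropout/BN inactive at inference
  # batch order: permuting rows permutes predictions
  perm <- rev(seq_len(dim(fs$x)[1]))
  p3 <- predict(net, fs$x[perm, , , , drop = FALSE], type = "prob")
  expect_equal(p3, p1[perm, ], tolerance = 1e-12)
  # single-item calls agree with the batch
  p_one <- predict(net, fs$x[3, , , , drop = FALSE], type = "prob")
  expect_equal(as.numeric(p_one), as.numeric(p1[3, ]), tolerance = 1e-12)
})

test_that("identically initialized modules on equal channel inputs match", {
  set.seed(6)
  net <- build_picnn(fx_tiny_spec())
  mods <- semgssr:::nn_collect(net$graph)
  chan <- Filter(function(e) identical(e$tag, "channel_concat"), mods)[[1]]
  # copy module 1 parameters into module 2
  n1 <- semgssr:::nn_collect(chan$mods[[1]])
  n2 <- semgssr:::nn_collect(chan$mods[[2]])
  for (i in seq_along(n1))
    for (f in semgssr:::nn_param_fields(n1[[i]]))
      n2[[i]][[f]] <- n1[[i]][[f]]
  xch <- array(rnorm(2 * 32 * 1 * 2), c(2, 32, 1, 2))
  o1 <- semgssr:::nn_forward(chan$mods[[1]], xch)
  o2 <- semgssr:::nn_forward(chan$mods[[2]], xch)
  expect_identical(o1, o2)
})
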