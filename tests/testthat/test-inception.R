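test_that("conv1d reproduces closed-form examples", {
  expect_equal(conv1d(c(1, 2, 3), c(1)), c(1, 2, 3))
  expect_equal(conv1d(c(1, 2, 3, 4), c(1, 1)), c(3, 5, 7))
  expect_equal(conv1d(1:6, c(1, 0, -1), stride = 2), c(-2, -2))
  # same-padding at stride 1 preserves length; even kernels pad right
  expect_length(conv1d(1:7, rep(1, 4), padding = "same"), 7)
  expect_equal(conv1d(c(1, 1, 1), c(1, 1), padding = "same"), c(2, 2, 1))
  expect_error(conv1d(1:3, numeric(0)), "nonempty")
  expect_error(conv1d(1:3, 1, stride = 0), "positive")
})

test_that("maxpool1d reproduces closed-form examples", {
  expect_equal(maxpool1d(c(1, 3, 2, 5), 2, stride = 2), c(3, 5))
  expect_equal(maxpool1d(1:6, 3, stride = 1), c(3, 4, 5, 6))
  expect_equal(maxpool1d(1:5, 3, stride = 1, padding = "same"),
               c(2, 3, 4, 5, 5))
  expect_equal(maxpool1d(rep(2, 6), 3, stride = 2), rep(2, 2))
  expect_error(maxpool1d(numeric(0), 2), "nonempty")
})

test_that("conv1d and maxpool1d agree with naive oracles on random cases", {
  set.seed(42)
  for (r in 1:60) {
    n <- sample(5:30, 1)
    K <- sample(1:5, 1)
    stride <- sample(1:3, 1)
    padding <- sample(c("valid", "same"), 1)
    x <- rnorm(n)
    k <- rnorm(K)
    if (padding == "valid" && n < K) next
    expect_equal(conv1d(x, k, stride, padding),
                 naive_conv1d(x, k, stride, padding))
    ps <- sample(1:4, 1)
    if (padding == "valid" && n < ps) next
    expect_equal(maxpool1d(x, ps, stride, padding),
                 naive_maxpool1d(x, ps, stride, padding))
  }
})

test_that("model specs validate their structural constraints", {
  expect_error(model_spec("II", inception = inception_spec()),
               "exactly two")
  expect_error(model_spec("I", inception = list(inception_spec(),
                                                inception_spec())),
               "exactly one")
  # expanded kernels only in the module fed the raw ECG input
  expect_error(model_spec("III", inception = inception_spec(c(10, 50, 100))),
               "directly on the ECG input")
  expect_error(
    model_spec("II", inception = list(inception_spec(),
                                      inception_spec(c(10, 50, 100)))),
    "directly on the ECG input")
  expect_s3_class(model_spec("I", inception = inception_spec(c(10, 50, 100), 9)),
                  "model_spec")
  expect_s3_class(
    model_spec("II", inception = list(inception_spec(c(10, 50, 100)),
                                      inception_spec())),
    "model_spec")
  expect_error(inception_spec(integer(0)), "at least one")
  expect_error(inception_spec(pool_size = 1), "pool_size")
})

test_that("build_model is deterministic and matches a hand parameter count", {
  spec <- model_spec("I", input_length = 50,
                     inception = inception_spec(c(1), 1),
                     fc_widths = c(2, 2))
  m1 <- build_model(spec, seed = 7)
  m2 <- build_model(spec, seed = 7)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_model(spec, seed = 8)
  expect_false(identical(m1$layers, m3$layers))
  # hand count: conv (1*1*1 + 1) = 2; channels 1 conv + 1 pool = 2;
  # flatten 50*2 = 100; dense 100*2+2; dense 2*2+2; out 2*5+5
  expect_equal(n_parameters(m1), 2 + (100 * 2 + 2) + (2 * 2 + 2) + (2 * 5 + 5))
  # design III front: conv 5*1*15+15; pool halves length; one inception
  spec3 <- model_spec("III", input_length = 40,
                      inception = inception_spec(c(1), 1),
                      cnn_filters = 15, fc_widths = c(2, 2))
  # conv valid: 40-5+1 = 36; pool 2/2: 18; channels 15 -> inception 1*1+15=16
  hand <- (5 * 15 + 15) + (1 * 15 * 1 + 1) +
    (18 * 16 * 2 + 2) + (2 * 2 + 2) + (2 * 5 + 5)
  expect_equal(n_parameters(build_model(spec3, seed = 1)), hand)
})

test_that("forward produces probability rows and honours batch shape", {
  m <- build_model(model_spec("I", inception = inception_spec(filters_per_branch = 3)),
                   seed = 3)
  X <- matrix(0, nrow = 4, ncol = 200)
  P <- forward(m, X)
  expect_equal(dim(P), c(4, 5))
  expect_true(all(is.finite(P)))
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-6)
  expect_equal(colnames(P), beat_classes())
  # batch of 100 length-200 inputs -> 100 x 5
  P100 <- forward(m, matrix(rnorm(100 * 200), 100, 200))
  expect_equal(dim(P100), c(100, 5))
  expect_equal(rowSums(P100), rep(1, 100), tolerance = 1e-6)
  expect_error(forward(m, matrix(0, 2, 150)), "input_length")
})

test_that("inception concatenation preserves length and channel count", {
  spec <- model_spec("II", input_length = 30,
                     inception = list(inception_spec(c(1, 3, 5), 4),
                                      inception_spec(c(1, 3), 2)))
  m <- build_model(spec, seed = 2)
  # channel accounting: module 1 emits 3*4 + 1 = 13 channels; module 2's
  # branch convolutions must therefore consume 13 input channels
  br <- m$layers[[2]]$branches
  expect_equal(dim(br[[1]]$W)[2], 13)
  # and module 2 emits 2*2 + 13 channels into the flatten layer
  flat_in <- dim(m$layers[[4]]$W)[1]
  expect_equal(flat_in, 30 * (2 * 2 + 13))
})

test_that("forward equals a naive per-channel dense recomputation", {
  spec <- model_spec("I", input_length = 12,
                     inception = inception_spec(c(1, 3), 2, pool_size = 3),
                     fc_widths = c(4, 3))
  m <- build_model(spec, seed = 11)
  set.seed(12)
  x <- rnorm(12)
  ly <- m$layers
  # inception by hand: conv branches (same padding, relu), then pool branch
  channels <- list()
  for (j in 1:2) {
    W <- ly[[1]]$branches[[j]]$W
    b <- ly[[1]]$branches[[j]]$b
    for (f in 1:2) {
      channels[[length(channels) + 1]] <-
        pmax(naive_conv1d(x, W[, 1, f], 1, "same") + b[f], 0)
    }
  }
  channels[[length(channels) + 1]] <- naive_maxpool1d(x, 3, 1, "same")
  vec <- unlist(channels)          # flatten: channel blocks in order
  for (d in c(2, 4)) {             # two hidden dense+relu layers
    W <- ly[[d + 1]]$W; b <- ly[[d + 1]]$b
    vec <- pmax(as.vector(vec %*% W) + b, 0)
  }
  W <- ly[[7]]$W; b <- ly[[7]]$b
  logits <- as.vector(vec %*% W) + b
  expected <- exp(logits - max(logits)) / sum(exp(logits - max(logits)))
  got <- forward(m, x)
  expect_equal(as.vector(got), expected, tolerance = 1e-12)
})

test_that("forward is deterministic given parameters and input", {
  m <- build_model(model_spec("I"), seed = 5)
  X <- matrix(rnorm(3 * 200), 3, 200)
  expect_identical(forward(m, X), forward(m, X))
})

test_that("models survive a save/load round trip", {
  dir <- withr::local_tempdir()
  m <- build_model(model_spec("III", input_length = 60,
                              inception = inception_spec(c(1, 3), 2),
                              fc_widths = c(6, 4)), seed = 9)
  save_model(m, file.path(dir, "m.json"))
  m2 <- load_model(file.path(dir, "m.json"))
  X <- matrix(rnorm(2 * 60), 2, 60)
  expect_equal(forward(m2, X), forward(m, X), tolerance = 1e-12)
  expect_equal(m2$spec, m$spec)
})
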