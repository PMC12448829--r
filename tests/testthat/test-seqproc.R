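test_that("preprocess_sequence truncates only beyond 1024 residues", {
  long <- paste(rep("A", 1500), collapse = "")
  expect_equal(nchar(preprocess_sequence(long)), 1000)
  edge <- paste(rep("A", 1024), collapse = "")
  expect_identical(preprocess_sequence(edge), edge)
  expect_identical(preprocess_sequence("MKV"), "MKV")
  expect_error(preprocess_sequence(""), class = "gofunnet_data_error")
})

test_that("embed_sequence enforces the adapter contract", {
  emb <- make_stub_embedder(8)
  e <- embed_sequence("ACD", emb)
  expect_equal(dim(e), c(3, 8))
  expect_identical(e, embed_sequence("ACD", emb))
  broken <- function(seq) stop("adapter exploded")
  expect_error(embed_sequence("ACD", broken, id = "P1"),
               regexp = "P1", class = "gofunnet_data_error")
  wrong <- function(seq) matrix(0, 1, 8)
  expect_error(embed_sequence("ACD", wrong), class = "gofunnet_data_error")
})

test_that("dcc_layer is causal, length-preserving and matches Eq-style sums", {
  # tap s=0 identity kernel
  x <- matrix(rnorm(20), 20, 1)
  expect_equal(dcc_layer(x, c(1, 0, 0), dilation = 3), x)
  # causality: perturbing position t+1 leaves outputs <= t unchanged
  set.seed(61)
  x <- matrix(rnorm(30), 30, 2)
  k <- lapply(1:3, function(i) matrix(rnorm(4), 2, 2))
  y <- dcc_layer(x, k, dilation = 2)
  x2 <- x; x2[15, ] <- x2[15, ] + 1
  y2 <- dcc_layer(x2, k, dilation = 2)
  expect_equal(y[1:14, ], y2[1:14, ])
  expect_false(isTRUE(all.equal(y[15, ], y2[15, ])))
  expect_equal(dim(y), dim(x))
})

test_that("dcc_layer equals the double-loop oracle on 50 random cases", {
  set.seed(67)
  for (i in 1:50) {
    L <- sample(5:25, 1); cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    S <- sample(2:4, 1); dil <- sample(1:4, 1)
    x <- matrix(rnorm(L * cin), L, cin)
    k <- lapply(seq_len(S), function(s) matrix(rnorm(cin * cout), cin, cout))
    b <- rnorm(cout)
    expect_equal(dcc_layer(x, k, b, dil), naive_dcc(x, k, b, dil),
                 tolerance = 1e-10)
  }
})

test_that("receptive fields follow the closed form and the impulse probe", {
  expect_equal(receptive_field(4), 31L)
  expect_equal(vapply(1:4, receptive_field, 1L), c(3L, 7L, 15L, 31L))
  expect_equal(receptive_field(1, 3, 1), 3L)
  expect_equal(receptive_field(2, 2, c(1, 2)), 4L)
  expect_error(receptive_field(5), class = "gofunnet_config_error")
  # empirical impulse response equals the closed form, several schedules
  expect_equal(measure_receptive_field(4), c(3L, 7L, 15L, 31L))
  expect_equal(measure_receptive_field(2, 2, c(1, 2), len = 16),
               vapply(1:2, receptive_field, 1L,
                      kernel_width = 2, dilations = c(1, 2)))
  expect_equal(measure_receptive_field(3, 2, c(2, 4, 8), len = 40),
               vapply(1:3, receptive_field, 1L,
                      kernel_width = 2, dilations = c(2, 4, 8)))
})

test_that("gated fusion obeys its analytic limits and keeps gates in (0,1)", {
  L <- 6; C <- 3; Q <- 2
  feats <- lapply(1:Q, function(q) matrix(rnorm(L * C), L, C))
  wz <- lapply(1:Q, function(q) matrix(0, Q * C, C))
  # zero gate weights: every gate is sigma(0) = 0.5
  out <- gated_multiscale_fusion(feats, wz)
  expect_equal(out, 0.5 * (feats[[1]] + feats[[2]]), tolerance = 1e-12)
  # large positive bias: gates ~ 1, plain sum
  out1 <- gated_multiscale_fusion(feats, wz, gate_b = rep(list(rep(50, C)), Q))
  expect_equal(out1, feats[[1]] + feats[[2]], tolerance = 1e-10)
  # single-scale zero-weight case: 0.5 x input
  expect_equal(gated_multiscale_fusion(feats[1], list(matrix(0, C, C))),
               0.5 * feats[[1]], tolerance = 1e-12)
  expect_error(gated_multiscale_fusion(list(feats[[1]],
                                            matrix(0, L + 1, C)), wz),
               class = "gofunnet_data_error")
})

test_that("global/local fusion matches the gate formula", {
  L <- 5; C <- 4
  set.seed(71)
  f1 <- matrix(rnorm(L * C), L, C); f2 <- matrix(rnorm(L * C), L, C)
  # W_g = 0: gate 0.5 everywhere
  expect_equal(fuse_global_local(f1, f2, matrix(0, 2 * C, C)),
               0.5 * (f1 + f2), tolerance = 1e-12)
  # random case against the direct formula
  wg <- matrix(rnorm(2 * C * C), 2 * C, C); bg <- rnorm(C)
  got <- fuse_global_local(f1, f2, wg, bg)
  gate <- 1 / (1 + exp(-(cbind(f1, f2) %*% wg +
                           matrix(bg, L, C, byrow = TRUE))))
  expect_equal(got, gate * (f1 + f2), tolerance = 1e-10)
  expect_true(all(gate > 0 & gate < 1))
  expect_error(fuse_global_local(f1, f2[, 1:2], wg),
               class = "gofunnet_data_error")
})

test_that("pooling reduces residues to one protein vector", {
  x <- matrix(c(1, 3, 2, 6), 2, 2)
  expect_equal(pool_to_protein(x), c(2, 4))
  expect_equal(pool_to_protein(x, "max"), c(3, 6))
  expect_equal(pool_to_protein(x[1, , drop = FALSE]), c(1, 2))
  const <- matrix(5, 7, 3)
  expect_equal(pool_to_protein(const), rep(5, 3))
})

test_that("the full stack stays causal under suffix zeroing", {
  # property: zeroing the input beyond position t never changes <= t
  set.seed(73)
  L <- 40
  x <- matrix(rnorm(L * 2), L, 2)
  k <- lapply(1:3, function(i) matrix(rnorm(4), 2, 2))
  stack_fwd <- function(x) {
    for (d in c(1, 2, 4, 8)) x <- dcc_layer(x, k, dilation = d)
    x
  }
  y <- stack_fwd(x)
  for (t in c(5, 20, 35)) {
    xz <- x; xz[(t + 1):L, ] <- 0
    expect_equal(stack_fwd(xz)[1:t, ], y[1:t, ], tolerance = 1e-12)
  }
})
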