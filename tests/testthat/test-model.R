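# forward with dropout forced off (gradient checks need a deterministic
# loss surface)
model_forward_nodes_for_test <- function(model, embs) {
  model$config$dropout <- 0
  gofunnet:::model_forward_nodes(model, embs, train = FALSE)
}

test_that("model_config validates and carries the reference defaults", {
  cfg <- model_config()
  expect_equal(cfg$epochs, 50L)
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$lr, 0.001)
  expect_equal(cfg$dropout, 0.2)
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$steps, 2L)
  expect_equal(cfg$evalue_threshold, 1e-10)
  expect_equal(cfg$dilations, c(1L, 2L, 4L, 8L))
  expect_error(model_config(dropout = 1), class = "gofunnet_config_error")
  expect_error(model_config(steps = 0), class = "gofunnet_config_error")
  expect_error(model_config(sparsity_ratio = 0),
               class = "gofunnet_config_error")
})

test_that("assembly is deterministic and the forward pass has logit shape", {
  w <- toy_world()
  cfg <- toy_overfit_config(epochs = 2L)
  m1 <- assemble_model(cfg, w$a_f, w$diff)
  m2 <- assemble_model(cfg, w$a_f, w$diff)
  expect_identical(m1$params, m2$params)
  ds <- toy_dataset()
  lg <- model_forward(m1, ds$embeddings)
  expect_equal(dim(lg), c(20, 10))
  expect_true(all(is.finite(lg)))
  expect_identical(lg, model_forward(m1, ds$embeddings))
})

test_that("parameter count matches the closed-form sum", {
  w <- toy_world()
  C <- 8L; K <- 16L; nf <- 10L; Q <- 4L; S <- 3L; N <- 2L; L <- 2L
  cfg <- model_config(channels = C, embed_dim = K, layers = L, steps = N)
  m <- assemble_model(cfg, w$a_f, w$diff)
  expected <- K * C +                                   # projection
    Q * (S * C * C + C) +                               # DCC kernels + bias
    Q * (Q * C * C + C) +                               # gates
    2 * C * C + C +                                     # fusion
    nf * C +                                            # function embedding
    L * 2 * (3 * C * C + 2) +                           # attention (2 sides)
    L * N * 5 * C * C +                                 # conv weights
    C * nf + nf                                         # head
  expect_equal(n_model_params(m), expected)
})

test_that("bce_with_logits_loss is exact, stable and validated", {
  expect_equal(bce_with_logits_loss(matrix(0), matrix(1)), log(2),
               tolerance = 1e-12)
  big <- bce_with_logits_loss(matrix(100), matrix(1))
  expect_true(is.finite(big) && big < 1e-10)
  expect_true(is.finite(bce_with_logits_loss(matrix(-1000), matrix(0))))
  # naive-formula oracle at moderate logits
  set.seed(131)
  x <- matrix(rnorm(40, sd = 3), 8, 5)
  y <- matrix(rbinom(40, 1, 0.5), 8, 5)
  naive <- -mean(y * log(plogis(x)) + (1 - y) * log(1 - plogis(x)))
  expect_equal(bce_with_logits_loss(x, y), naive, tolerance = 1e-8)
  expect_error(bce_with_logits_loss(x, y + 0.5),
               class = "gofunnet_data_error")
  # the printed variant is a different function
  expect_false(isTRUE(all.equal(bce_printed_variant(x, y),
                                bce_with_logits_loss(x, y))))
})

test_that("analytic gradients match finite differences on a micro model", {
  ms <- micro_setup()
  model <- ms$model
  labels <- as.matrix(ms$dataset$labels)
  loss_at <- function(params) {
    m2 <- model
    m2$params <- params
    fw <- model_forward_nodes_for_test(m2, ms$dataset$embeddings)
    bce_with_logits_loss(fw$logits$value, labels)
  }
  fw <- model_forward_nodes_for_test(model, ms$dataset$embeddings)
  loss <- gofunnet:::ad_bce_logits(fw$logits, labels)
  gofunnet:::ad_backward(loss)
  eps <- 1e-5
  set.seed(137)
  for (nm in sample(names(model$params), 12)) {
    g <- fw$params[[nm]]$grad
    if (is.null(g)) next
    i <- sample(length(model$params[[nm]]), 1)
    pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    denom <- max(abs(num), abs(g[i]), 1e-8)
    expect_lt(abs(num - g[i]) / denom, 1e-4)
  }
})

test_that("training is seeded-deterministic and aborts on missing labels", {
  w <- toy_world()
  ds <- toy_dataset()
  cfg <- toy_overfit_config(epochs = 3L)
  m1 <- train_model(assemble_model(cfg, w$a_f, w$diff), ds)
  m2 <- train_model(assemble_model(cfg, w$a_f, w$diff), ds)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_length(m1$history, 3)
  expect_false(is.null(m1$best$epoch))
  expect_error(build_dataset(w$prot, w$lab[1:5, ], make_stub_embedder(16)),
               class = "gofunnet_data_error")
})

test_that("predictions are probabilities and rank positives above negatives", {
  m <- toy_trained()
  ds <- toy_dataset()
  sc <- predict_scores(m, ds)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_identical(sc, predict_scores(m, ds))   # dropout off at inference
  lab <- toy_world()$lab
  expect_gt(mean(sc[lab == 1]), mean(sc[lab == 0]))
  expect_gt(roc_auc(as.numeric(sc), as.numeric(lab)), 0.95)
})

test_that("split_dataset keeps a training positive for every term", {
  set.seed(139)
  lab <- matrix(rbinom(200, 1, 0.15), 40, 5)
  lab[rowSums(lab) == 0, 1] <- 1
  sp <- split_dataset(lab, ratio = 0.8, seed = 1)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sort(c(sp$train, sp$test)), 1:40)
  expect_true(all(colSums(lab[sp$train, , drop = FALSE]) >= 1))
})

test_that("prediction export round-trips through the CAFA-style TSV", {
  m <- toy_trained()
  sc <- predict_scores(m, toy_dataset())
  path <- withr::local_tempfile()
  write_predictions(sc, path)
  back <- read_predictions(path, rownames(sc), colnames(sc))
  expect_equal(back, round(sc, 6), tolerance = 1e-12)
})

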