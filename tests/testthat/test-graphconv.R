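id_params <- function(C, steps, n_terms) {
  lapply(seq_len(n_terms), function(i)
    lapply(seq_len(steps), function(n) diag(C)))
}

test_that("function block obeys identity and zero limits", {
  set.seed(101)
  nf <- 4; np <- 3; C <- 2
  x <- random_hidden_state(nf, np, C)
  # N=1, prior = I, attention = 0, W11 = I -> Z = X
  pr <- list(list(diag(C)), list(matrix(0, C, C)))
  z <- function_graph_conv(x, diag(nf), matrix(0, nf, nf), pr,
                           normalize = FALSE)
  expect_equal(z, x, tolerance = 1e-12)
  # zero prior and zero attention -> zero output
  pz <- graphconv_params(C, C, steps = 2, n_terms = 2, seed = 1)
  z0 <- function_graph_conv(x, matrix(0, nf, nf), matrix(0, nf, nf), pz)
  expect_equal(sum(abs(z0)), 0)
})

test_that("protein block symmetry and identity limits hold", {
  set.seed(103)
  nf <- 3; np <- 4; C <- 2
  x <- random_hidden_state(nf, np, C)
  # R_f = R_b = I, attention 0, U11 = U12 = I/2 -> Z = X
  pr <- list(list(diag(C) / 2), list(diag(C) / 2), list(matrix(0, C, C)))
  z <- protein_graph_conv(x, list(forward = diag(np), backward = diag(np)),
                          matrix(0, np, np), pr)
  expect_equal(z, x, tolerance = 1e-12)
  # symmetric adjacency: forward and backward terms coincide when weights
  # are shared
  a <- matrix(0, np, np); a[1, 2] <- a[2, 1] <- 1; a[3, 4] <- a[4, 3] <- 1
  d <- diffusion_matrices(a)
  u <- graphconv_params(C, C, steps = 2, n_terms = 1, seed = 5)[[1]]
  zf <- protein_graph_conv(
    x, d, matrix(0, np, np), list(u, list(matrix(0, C, C),
                                          matrix(0, C, C)),
                                  list(matrix(0, C, C), matrix(0, C, C))))
  zb <- protein_graph_conv(
    x, d, matrix(0, np, np), list(list(matrix(0, C, C), matrix(0, C, C)),
                                  u, list(matrix(0, C, C),
                                          matrix(0, C, C))))
  expect_equal(zf, zb, tolerance = 1e-12)
})

test_that("both blocks match the brute-force power-sum oracle", {
  set.seed(107)
  for (i in 1:25) {
    nf <- sample(2:5, 1); np <- sample(2:5, 1)
    cin <- sample(2:3, 1); cout <- sample(2:3, 1)
    x <- random_hidden_state(nf, np, cin)
    af <- matrix(rbinom(nf * nf, 1, 0.4), nf, nf); diag(af) <- 0
    fat <- naive_topk_softmax(matrix(rnorm(nf * nf), nf, nf),
                              max(1, nf %/% 2))
    wf <- graphconv_params(cin, cout, steps = 2, n_terms = 2, seed = i)
    got <- function_graph_conv(x, af, fat, wf)
    afn <- af / pmax(rowSums(af), 1)
    ref <- naive_diffusion(x, list(afn, fat), wf, 2, "function")
    expect_equal(got, ref, tolerance = 1e-8)

    ap <- matrix(rbinom(np * np, 1, 0.5), np, np)
    ap <- 1 * ((ap + t(ap)) > 0); diag(ap) <- 0
    d <- diffusion_matrices(ap)
    pat <- naive_topk_softmax(matrix(rnorm(np * np), np, np),
                              max(1, np %/% 4))
    up <- graphconv_params(cin, cout, steps = 2, n_terms = 3, seed = i + 100)
    gotp <- protein_graph_conv(x, d, pat, up)
    refp <- naive_diffusion(x, list(d$forward, d$backward, pat), up, 2,
                            "protein")
    expect_equal(gotp, refp, tolerance = 1e-8)
  }
})

test_that("adaptive-only variants drop the prior terms consistently", {
  set.seed(109)
  nf <- 4; np <- 5; C <- 2
  x <- random_hidden_state(nf, np, C)
  fat <- naive_topk_softmax(matrix(rnorm(nf * nf), nf, nf), 2)
  wf <- graphconv_params(C, C, steps = 2, n_terms = 2, seed = 11)
  expect_equal(function_graph_conv_adaptive_only(x, fat, wf),
               function_graph_conv(x, matrix(0, nf, nf), fat, wf),
               tolerance = 1e-12)
  # N=1 reduces to a single mixed product
  w1 <- list(list(matrix(rnorm(C * C), C, C)))
  z <- function_graph_conv_adaptive_only(x, fat, w1)
  ref <- naive_diffusion(x, list(fat), w1, 1, "function")
  expect_equal(z, ref, tolerance = 1e-10)

  pat <- naive_topk_softmax(matrix(rnorm(np * np), np, np), 2)
  up <- graphconv_params(C, C, steps = 2, n_terms = 3, seed = 13)
  zer <- list(forward = matrix(0, np, np), backward = matrix(0, np, np))
  expect_equal(protein_graph_conv_adaptive_only(x, pat, up),
               protein_graph_conv(x, zer, pat, up), tolerance = 1e-12)
})

test_that("priors are never modified and the conv is linear in x", {
  set.seed(113)
  nf <- 4; np <- 4; C <- 2
  x <- random_hidden_state(nf, np, C)
  y <- random_hidden_state(nf, np, C)
  af <- matrix(rbinom(nf * nf, 1, 0.5), nf, nf); diag(af) <- 0
  af_copy <- af + 0
  fat <- naive_topk_softmax(matrix(rnorm(nf * nf), nf, nf), 2)
  w <- graphconv_params(C, C, steps = 2, n_terms = 2, seed = 17)
  z1 <- function_graph_conv(x, af, fat, w)
  expect_identical(af, af_copy)
  # linearity: conv(a x + b y) = a conv(x) + b conv(y)
  z2 <- function_graph_conv(y, af, fat, w)
  z3 <- function_graph_conv(2 * x - 3 * y, af, fat, w)
  expect_equal(z3, 2 * z1 - 3 * z2, tolerance = 1e-10)
})

test_that("N-step locality: influence travels at most N hops", {
  # chain graph 1-2-3-4-5, N = 2: node 1 must not feel node 5
  np <- 5; nf <- 2; C <- 2
  a <- matrix(0, np, np)
  for (i in 1:4) { a[i, i + 1] <- 1; a[i + 1, i] <- 1 }
  d <- diffusion_matrices(a)
  u <- graphconv_params(C, C, steps = 2, n_terms = 3, seed = 19)
  set.seed(127)
  x <- random_hidden_state(nf, np, C)
  x2 <- x; x2[, 5, ] <- x2[, 5, ] + 10
  patt <- matrix(0, np, np)       # no attention shortcuts
  z1 <- protein_graph_conv(x, d, patt, u)
  z2 <- protein_graph_conv(x2, d, patt, u)
  expect_equal(z1[, 1:2, ], z2[, 1:2, ], tolerance = 1e-10)  # > 2 hops away
  expect_false(isTRUE(all.equal(z1[, 3, ], z2[, 3, ])))      # 2 hops
})
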