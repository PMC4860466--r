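test_that("the Hebbian increment is beta * alpha_k * alpha_l * N", {
  W <- matrix(0, 1, 1)
  expect_equal(hebbian_update(W, 1, 1, agreement = 0.8125)[1, 1], 0.1625)
  expect_equal(hebbian_update(W, 1, 1, agreement = 0.1875)[1, 1], 0.0375)
  ## general random case against the closed form
  set.seed(3)
  a <- runif(4); b <- runif(5); W0 <- matrix(runif(20) * 0.3, 4, 5)
  W1 <- hebbian_update(W0, a, b, agreement = 0.6, beta = 0.2)
  expect_equal(W1, W0 + 0.2 * 0.6 * outer(a, b))
  ## silent source nodes leave their rows untouched
  a[2] <- 0
  W1 <- hebbian_update(W0, a, b, agreement = 0.6)
  expect_equal(W1[2, ], W0[2, ])
  expect_error(hebbian_update(W0, a, b, agreement = -0.1),
               class = "bilexnet_bad_agreement")
  expect_error(hebbian_update(W0, runif(3), b, agreement = 0.5),
               class = "bilexnet_dim_mismatch")
})

test_that("multiplicative normalisation caps outgoing vectors at 1", {
  ## an update pushing a weight past 1 rescales that row so its max is 1
  W <- matrix(c(1.0, 0.5), 1, 2)
  W1 <- hebbian_update(W, 1, c(1, 0), agreement = 1, beta = 0.2)
  expect_equal(max(W1), 1)
  expect_equal(W1[1, ], c(1.2, 0.5) / 1.2)
  ## closed form before the cap: t identical co-activations give t*beta*N
  W <- matrix(0, 1, 1)
  for (t_ in 1:4) W <- hebbian_update(W, 1, 1, agreement = 0.5, beta = 0.2)
  expect_equal(W[1, 1], 4 * 0.2 * 0.5)
  ## long random update sequences never escape [0, 1]
  set.seed(8)
  W <- matrix(0, 5, 5)
  for (k in 1:50)
    W <- hebbian_update(W, runif(5), runif(5), agreement = runif(1))
  expect_true(all(W >= 0 & W <= 1))
})

test_that("propagation is a clipped weighted sum", {
  expect_equal(propagate(rep(0, 3), matrix(runif(9), 3)), rep(0, 3))
  W <- diag(3)
  a <- c(0.2, 0.7, 1)
  expect_equal(propagate(a, W), a)
  set.seed(5)
  for (k in 1:100) {
    W <- matrix(runif(16) * 0.5, 4)
    a <- runif(4)
    expect_equal(propagate(a, W), pmin(pmax(as.numeric(a %*% W), 0), 1))
  }
  expect_error(propagate(runif(3), matrix(0, 4, 4)),
               class = "bilexnet_dim_mismatch")
})

test_that("lateral connections strengthen cross-language co-activations only", {
  L <- lateral_matrix(nodes = c(3L, 8L, 15L), language = c("A", "A", "B"),
                      n_map = 20L)
  fa <- numeric(20); fb <- numeric(20)
  ## one language silent: no change
  fa[3] <- 1
  L1 <- lateral_update(L, fa, fb)
  expect_equal(L1$weights, L$weights)
  ## a single co-activated pair gets beta in both directions
  fb[15] <- 1
  L1 <- lateral_update(L, fa, fb, beta = 0.2)
  expect_equal(L1$weights[1, 3], 0.2)
  expect_equal(L1$weights[3, 1], 0.2)
  expect_equal(L1$weights[2, 3], 0)        # silent A word untouched
  expect_equal(diag(L1$weights), rep(0, 3))
  ## repeated co-activation increases strictly up to the cap
  prev <- 0
  for (k in 1:10) {
    L <- lateral_update(L, fa, fb, beta = 0.2)
    w <- L$weights[1, 3]
    expect_gt(w, prev - 1e-12)
    expect_lte(w, 1)
    prev <- w
  }
  ## propagation reads the other language's nodes
  out <- lateral_propagate(L, fa, from = "A")
  expect_equal(which(out > 0), 15L)
  ## overlapping node sets are rejected
  expect_error(lateral_matrix(c(3L, 3L), c("A", "B"), 20L),
               class = "bilexnet_overlapping_nodes")
  bad <- numeric(20); bad[15] <- 0.5
  expect_error(lateral_update(L, bad, fb), class = "bilexnet_overlapping_nodes")
})

test_that("the fast lazily-scaled Hebbian path matches the reference update", {
  set.seed(13)
  n <- 6
  for (trial in 1:20) {
    a_env <- bilexnet:::.assoc_new(n, n)
    W_ref <- matrix(0, n, n)
    for (k in 1:15) {
      src <- sort(sample.int(n, 3))
      tgt <- sort(sample.int(n, 3))
      as_ <- runif(3); at_ <- runif(3); N <- runif(1)
      full_src <- numeric(n); full_src[src] <- as_
      full_tgt <- numeric(n); full_tgt[tgt] <- at_
      W_ref <- hebbian_update(W_ref, full_src, full_tgt, agreement = N)
      bilexnet:::cpp_hebb(a_env$W, a_env$scale, a_env$rowmax,
                          src - 1L, as_, tgt - 1L, at_ * N, 0.2)
    }
    expect_equal(bilexnet:::.assoc_eff(a_env), W_ref, tolerance = 1e-12)
  }
})
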