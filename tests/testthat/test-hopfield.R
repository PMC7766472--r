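# Hebbian storage, recall dynamics, energy function and fixed points.

test_that("Hebb training reproduces hand-computed weights", {
  # single all-+1 pattern: off-diagonal 1, zero diagonal
  net <- hopfield(rep(1, 25))
  expect_equal(diag(net$weights), rep(0, 25))
  expect_true(all(net$weights[upper.tri(net$weights)] == 1))
  # sign cancels: p and -p give the same weights
  p <- rand_template(1)$vector
  expect_equal(hopfield(p)$weights, hopfield(-p)$weights)
  # two 4-neuron patterns, hand-summed outer products
  W <- hopfield(rbind(c(1, 1, -1, -1), c(1, -1, 1, -1)))$weights
  expect_equal(W[1, 2], 0)
  expect_equal(W[1, 3], 0)
  expect_equal(W[1, 4], -2)
  expect_equal(W[2, 3], -2)
  # eta scales weights linearly
  expect_equal(hopfield(p, eta = 0.5)$weights, 0.5 * hopfield(p)$weights)
})

test_that("Hebb training validates its inputs", {
  expect_error(hopfield(c(1, 0, -1)), "bipolar")
  expect_error(hopfield(list(c(1, -1), c(1, -1, 1))), "unequal lengths")
  expect_error(hopfield(rep(1, 25), eta = 0), "eta")
})

test_that("Hebb weights are symmetric with zero diagonal for random pattern sets", {
  set.seed(7)
  for (trial in 1:20) {
    q <- sample(1:5, 1)
    P <- matrix(rand_bipolar(q * 25), q)
    W <- hopfield(P)$weights
    expect_identical(W, t(W))
    expect_equal(diag(W), rep(0, 25))
  }
})

test_that("a stored pattern is recalled immediately with the closed-form fields", {
  p <- rand_template(2)$vector
  net <- hopfield(p)
  expect_equal(as.vector(coef(net) %*% p), 24 * p)  # u_i = (N-1) eta p_i
  r <- recall(net, p, seed = 1)
  expect_true(r$converged)
  expect_equal(r$sweeps, 1L)
  expect_equal(r$state, p)
  expect_true(is_fixed_point(net, p))
  expect_true(is_fixed_point(net, -p))              # sign symmetry at I = 0
})

test_that("single-bit corruption is corrected in one synchronous sweep", {
  p <- rand_template(3)$vector
  net <- hopfield(p)
  for (bit in c(1, 13, 25)) {
    probe <- p; probe[bit] <- -probe[bit]
    r <- recall(net, probe, mode = "sync")
    expect_equal(r$state, p)
    expect_lte(r$sweeps, 2L)
  }
})

test_that("zero weights and zero input keep the probe unchanged (tie rule)", {
  W <- matrix(0, 10, 10)
  set.seed(4)
  init <- rand_bipolar(10)
  for (mode in c("async", "sync")) {
    r <- recall(W, init, mode = mode, seed = 9)
    expect_equal(r$state, init)
    expect_true(r$converged)
  }
})

test_that("recall is invariant to the learning rate", {
  p <- rand_template(5)$vector
  probe <- p; probe[c(2, 9, 17)] <- -probe[c(2, 9, 17)]
  states <- lapply(c(0.1, 1, 7.5), function(eta) {
    recall(hopfield(p, eta = eta), probe, seed = 11)$state
  })
  expect_equal(states[[1]], states[[2]])
  expect_equal(states[[2]], states[[3]])
})

test_that("energy matches closed forms and is minimized at the stored pattern", {
  p <- rand_template(6)$vector
  net <- hopfield(p)
  # all 600 off-diagonal terms contribute +1: E = -(25^2 - 25)/2
  expect_equal(energy(net, p), -300)
  v <- rand_bipolar(25)
  expect_equal(energy(net, v), energy(net, -v))     # quadratic symmetry at I=0
  # N=3: enumerate all 8 states, stored pattern attains the minimum
  p3 <- c(1, -1, 1)
  net3 <- hopfield(p3)
  states <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  E <- apply(states, 1, function(v) energy(net3, v))
  expect_equal(min(E), energy(net3, p3))
})

test_that("asynchronous energy traces never increase", {
  set.seed(12)
  for (trial in 1:50) {
    W <- rand_symmetric_weights(25)
    r <- recall(W, rand_bipolar(25), mode = "async", seed = trial)
    expect_true(all(diff(r$energy) <= 1e-9))
  }
})

test_that("heavily mixed states engage the tie rule on zero-field neurons", {
  # flipping m=12 of 25 bits zeroes the field on uncorrupted neurons
  # (24 - 2m = 0), which must keep their state; corrupted neurons see field
  # (26 - 2m) p_i > 0 and flip back, so one sweep still restores the pattern
  p <- rand_template(8)$vector
  net <- hopfield(p)
  set.seed(21)
  flip <- sample(25, 12)
  probe <- p; probe[flip] <- -probe[flip]
  u <- as.vector(coef(net) %*% probe)
  expect_equal(u[-flip], rep(0, 13))
  r <- recall(net, probe, mode = "sync")
  expect_equal(r$state, p)
})

test_that("recall rejects malformed probes and weights", {
  net <- hopfield(rand_template(9)$vector)
  expect_error(recall(net, c(rep(1, 24), 0)), "bipolar")
  A <- matrix(rnorm(25), 5); diag(A) <- 0
  expect_error(recall(A, rand_bipolar(5)), "symmetric")
  S <- rand_symmetric_weights(5); diag(S) <- 1
  expect_error(recall(S, rand_bipolar(5)), "zero diagonal")
})

test_that("exhaustive fixed points agree with single-sweep recall on a small net", {
  set.seed(33)
  P <- matrix(rand_bipolar(2 * 6), 2)
  net <- hopfield(P)
  fps <- fixed_points(net)
  states <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  dimnames(states) <- NULL
  immediate <- states[apply(states, 1, function(v) {
    r <- recall(net, v, seed = 1)
    r$converged && r$sweeps == 1L && all(r$state == v)
  }), , drop = FALSE]
  expect_equal(fps[order(fps %*% 2^(0:5)), ],
               immediate[order(immediate %*% 2^(0:5)), ])
})
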