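# Cosine-similarity matching and the confusion-count evaluation.

test_that("cosine similarity matches the bipolar Hamming closed form", {
  a <- rand_template(20)$vector
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, -a), -1)
  b <- a; b[1:5] <- -b[1:5]                      # hamming distance 5 on 25 bits
  expect_equal(cosine_similarity(a, b), 0.6)     # (25 - 10) / 25
  expect_error(cosine_similarity(a, rep(0, 25)), "zero vector")
  expect_error(cosine_similarity(a, a[1:10]))
})

test_that("the Hamming identity holds exhaustively for N = 8 and on random pairs", {
  states <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  dimnames(states) <- NULL
  # dot products of all 256 x 256 pairs at once; cos = dot/8, hamming = (8-dot)/2
  dots <- states %*% t(states)
  expect_true(all(dots / 8 == (8 - 2 * ((8 - dots) / 2)) / 8))
  # the function itself on a random sample of pairs
  set.seed(71)
  for (k in 1:200) {
    i <- sample(256, 1); j <- sample(256, 1)
    h <- sum(states[i, ] != states[j, ])
    expect_equal(cosine_similarity(states[i, ], states[j, ]), (8 - 2 * h) / 8)
  }
})

test_that("fall decisions threshold the similarity to the fall template", {
  tpl <- rand_template(22, label = "Fall")
  res <- classify_sample(tpl$vector, tpl, threshold = 0.8)
  expect_true(res$positive)
  expect_equal(unname(res$confidence), 1)
  expect_equal(res$predicted, "Fall")

  neg <- classify_sample(-tpl$vector, tpl, threshold = 0.8)
  expect_false(neg$positive)
  expect_equal(unname(neg$confidence), -1)
  expect_equal(neg$predicted, "negative")

  v <- tpl$vector; v[1:5] <- -v[1:5]             # similarity 0.6 < 0.8
  expect_false(classify_sample(v, tpl, threshold = 0.8)$positive)
  expect_true(classify_sample(v, tpl, threshold = 0.6)$positive)
})

test_that("multi-class prediction is argmax with lexicographic ties", {
  fall <- rand_template(23, label = "Fall")
  walk <- template(-fall$grid, label = "Walk")
  res <- classify_sample(fall$vector, list(fall, walk))
  expect_equal(res$predicted, "Fall")
  expect_equal(unname(res$similarities["Walk"]), -1)
  # a probe equidistant from two templates ties; lexicographic order decides
  set.seed(77)
  a <- rand_bipolar(25)
  res_tie <- classify_sample(a, list(Zeta = a, Alpha = a),
                             positive_label = "Alpha")
  expect_equal(res_tie$predicted, "Alpha")
  expect_error(classify_sample(a, list(Walk = walk)), "positive")
  expect_error(classify_sample(a, list(Fall = fall), threshold = 1.5))
})

test_that("confusion counts and accuracy follow the printed formula", {
  rep1 <- evaluate_decisions(c(TRUE, FALSE, TRUE, FALSE),
                             c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rep1[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  expect_equal(rep1$accuracy, 0.5)
  expect_equal(evaluate_decisions(rep(c(TRUE, FALSE), 5),
                                  rep(c(TRUE, FALSE), 5))$accuracy, 1)
  # TP=8 TN=8 FP=1 FN=1 -> 16/18
  truth <- c(rep(TRUE, 9), rep(FALSE, 9))
  decision <- c(rep(TRUE, 8), FALSE, rep(FALSE, 8), TRUE)
  expect_equal(evaluate_decisions(truth, decision)$accuracy, 16 / 18)
  # label interface counts "Fall" as positive
  expect_equal(evaluate_decisions(c("Fall", "Walk"), c(TRUE, FALSE))$accuracy, 1)
  expect_error(evaluate_decisions(logical(0), logical(0)), "at least one")
})

test_that("evaluation is permutation-invariant and monotone in the threshold", {
  set.seed(81)
  truth <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  sims <- round(runif(40, -1, 1), 2)
  perm <- sample(40)
  base <- evaluate_decisions(truth, sims >= 0.5)
  expect_equal(unclass(evaluate_decisions(truth[perm], (sims >= 0.5)[perm])),
               unclass(base))
  # raising the threshold never raises TP and never lowers TN
  thresholds <- seq(-1, 1, by = 0.25)
  reps <- lapply(thresholds, function(th) evaluate_decisions(truth, sims >= th))
  expect_true(all(diff(vapply(reps, `[[`, 0L, "TP")) <= 0))
  expect_true(all(diff(vapply(reps, `[[`, 0L, "TN")) >= 0))
})
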