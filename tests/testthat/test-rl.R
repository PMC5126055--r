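test_that("value is the D1 weight of the selected deck", {
  w <- make_weights(d1 = c(0.2, 0.5, 0.7, 0.1))
  expect_identical(compute_value(w, "C"), 0.7)
  expect_identical(compute_value(w, c(0, 0, 1, 0)), 0.7)
  expect_identical(compute_value(make_weights(d1 = rep(0, 4)), "A"), 0)
  # permuting non-selected entries leaves the value unchanged
  w2 <- make_weights(d1 = c(0.5, 0.1, 0.7, 0.2))
  expect_identical(compute_value(w2, "C"), compute_value(w, "C"))
  expect_error(compute_value(w, c(1, 1, 0, 0)), "one-hot")
  expect_error(compute_value(w, c(0, 0, 0, 0)), "one-hot")
})

test_that("the TD error is reward plus loss minus value", {
  expect_identical(compute_delta(0, 0, 0), 0)
  expect_identical(compute_delta(100, -250, 20), -170)
  expect_identical(compute_delta(0.5, 0, 0.5), 0)  # fully predicted reward
  expect_error(compute_delta(1, 0.5, 0), "<= 0")
})

test_that("condition transforms implement clamp and medication arithmetic", {
  hc <- dopamine_params("HC")
  off <- dopamine_params("PD_OFF", da_ceil = 0.1)
  on <- dopamine_params("PD_ON_LDOPA", da_ceil = 0.1, delta_med = 2)
  daa <- dopamine_params("PD_ON_DAA", da_ceil = 0.1, delta_med = 2)
  expect_identical(condition_transform(5, hc), 5)
  expect_identical(condition_transform(-3, hc), -3)
  expect_identical(condition_transform(5, off), 0.1)
  expect_identical(condition_transform(-3, off), -3)   # min passes negatives
  expect_identical(condition_transform(-3, on), -1)
  expect_identical(condition_transform(-3, daa), -1)
  expect_identical(condition_transform(5, on), 2.1)
})

test_that("weight updates apply opposed plasticity to the selected deck", {
  dp <- dopamine_params("HC", eta = 0.1)
  w <- make_weights(d1 = rep(0.5, 4), d2 = rep(0.5, 4))
  w2 <- update_weights(w, 1, "A", dp)
  expect_equal(w2$d1[["A"]], 0.6)
  expect_equal(w2$d2[["A"]], 0.4)
  expect_identical(w2$d1[2:4], w$d1[2:4])
  expect_identical(w2$d2[2:4], w$d2[2:4])
  # delta = 0 changes nothing
  expect_identical(update_weights(w, 0, "B", dp), w)
})

test_that("the dopamine agonist freezes the D1 pathway", {
  dp <- dopamine_params("PD_ON_DAA")
  w <- make_weights()
  w2 <- update_weights(w, 1, "A", dp)
  expect_identical(w2$d1, w$d1)
  expect_equal(w2$d2[["A"]], 0.4)
})

test_that("opposed plasticity holds for arbitrary deltas and weights are bounded", {
  dp <- dopamine_params("HC", eta = 0.1)
  set.seed(31)
  for (k in 1:25) {
    w <- make_weights(d1 = runif(4, 0.3, 1.7), d2 = runif(4, 0.3, 1.7))
    delta <- runif(1, -2, 2)
    deck <- sample(c("A", "B", "C", "D"), 1)
    w2 <- update_weights(w, delta, deck, dp)
    dd1 <- w2$d1 - w$d1
    dd2 <- w2$d2 - w$d2
    expect_equal(dd1, -dd2)  # interior weights, no clipping active
    expect_true(all(w2$d1 >= 0 & w2$d1 <= 2))
    expect_true(all(w2$d2 >= 0 & w2$d2 <= 2))
  }
  # clipping engages at the bounds
  wlo <- make_weights(d1 = rep(0.01, 4))
  expect_equal(update_weights(wlo, -5, "A", dp)$d1[["A"]], 0)
  whi <- make_weights(d1 = rep(1.99, 4))
  expect_equal(update_weights(whi, 5, "A", dp)$d1[["A"]], 2)
})

test_that("the literal all-decks input variant updates every deck", {
  dp <- dopamine_params("HC", eta = 0.1)
  w <- make_weights()
  w2 <- update_weights(w, 1, "A", dp, literal_input = TRUE)
  expect_equal(unname(w2$d1), rep(0.6, 4))
  expect_equal(unname(w2$d2), rep(0.4, 4))
})

test_that("weights initialise uniformly on (0, 1)", {
  set.seed(2)
  w <- init_weights()
  expect_s3_class(w, "cs_weights")
  expect_true(all(w$d1 > 0 & w$d1 < 1 & w$d2 > 0 & w$d2 < 1))
  expect_identical(names(w$d1), c("A", "B", "C", "D"))
  set.seed(77); a <- init_weights()
  set.seed(77); b <- init_weights()
  expect_identical(a, b)
})

test_that("healthy TD learning ranks advantageous decks above disadvantageous", {
  # closed-loop-free check of the learning rule's direction: decks sampled
  # uniformly for 100 trials, healthy updates; value estimates should end
  # ordered by expected deck value over repeated seeds
  s <- deck_schedule()
  cfg_scale <- 0.01
  dp <- dopamine_params("HC")
  diffs <- vapply(1:12, function(seed) {
    set.seed(seed)
    w <- init_weights()
    for (k in 1:100) {
      deck <- sample(c("A", "B", "C", "D"), 1)
      card <- draw_card(s, deck, k)
      v <- compute_value(w, deck)
      d <- compute_delta(card$reward * cfg_scale, card$loss * cfg_scale, v)
      w <- update_weights(w, condition_transform(d, dp), deck, dp)
    }
    # deck B's rare large loss makes its D1 weight ratchet between
    # crashes, so the clean contrast is against deck A (frequent losses);
    # avoidance of A also accrues on the D2 side
    c(go = mean(w$d1[c("C", "D")]) - w$d1[["A"]],
      nogo = w$d2[["A"]] - mean(w$d2[c("C", "D")]))
  }, numeric(2))
  expect_lt(t.test(diffs["go", ], alternative = "greater")$p.value, 0.05)
  expect_lt(t.test(diffs["nogo", ], alternative = "greater")$p.value, 0.05)
})

test_that("medication reverses punishment learning on net-loss trials", {
  # the default medication term exceeds the largest scaled penalty, so even
  # the worst card (deck B, -1250 points -> -12.5) yields a positive
  # effective error and the disadvantageous deck is reinforced
  dp <- dopamine_params("PD_ON_LDOPA")
  w <- make_weights(d1 = c(0.5, 0.4, 0.5, 0.5))
  d <- compute_delta(1, -12.5, compute_value(w, "B"))
  expect_lt(d, 0)
  deff <- condition_transform(d, dp)
  expect_gt(deff, 0)
  w2 <- update_weights(w, deff, "B", dp)
  expect_gt(w2$d1[["B"]], w$d1[["B"]])
})
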