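# Source-ratio weighting, fallback, most-confident consensus.

test_that("ratio parsing and weight accounting follow a:b of total effective weight", {
  r <- parse_ratio("2:5")
  expect_equal(r$public, 2); expect_equal(r$private, 5)
  expect_error(parse_ratio("2:5:1"), "a:b")
  expect_error(source_ratio(0, 0), "not both zero")
  ms <- toy_labelled_molset()
  pub <- subset_mol_set(ms, 1:8)    # 8 public records
  priv <- subset_mol_set(ms, 9:12)  # 4 private records
  wts <- weighted_training_set(pub, priv, "1:1")
  w <- wts$weights
  # each source carries half the total weight; per-record private weight is
  # |public|/|private| times a public record's
  expect_equal(sum(w[1:8]), sum(w[9:12]))
  expect_equal(unique(w[9:12]) / unique(w[1:8]), 2)
  expect_equal(mean(w), 1)
})

test_that("ratio extremes reproduce single-source models bit-for-bit", {
  ms <- toy_labelled_molset()
  pub <- subset_mol_set(ms, c(1:3, 7:9))
  priv <- subset_mol_set(ms, c(4:6, 10:12))
  w50 <- weighted_training_set(pub, priv, "5:0", seed = 9)
  w05 <- weighted_training_set(pub, priv, "0:5", seed = 9)
  expect_identical(w50$data$df, pub$df)
  expect_identical(w05$data$df, priv$df)
  m_pub <- train_rf(pub, num_trees = 80, seed = 9)
  m_50 <- train_rf(w50$data, weights = w50$weights, num_trees = 80, seed = 9)
  expect_equal(predict(m_pub, ms), predict(m_50, ms))
  s_priv <- sohn_train(priv, min_support = 2, seed = 9)
  s_05 <- sohn_train(w05$data, weights = w05$weights, min_support = 2,
                     seed = 9)
  expect_equal(predict(s_priv, ms), predict(s_05, ms))
})

test_that("resampling mode is deterministic at a fixed seed", {
  ms <- toy_labelled_molset()
  pub <- subset_mol_set(ms, 1:8); priv <- subset_mol_set(ms, 9:12)
  r1 <- weighted_training_set(pub, priv, "2:5", mode = "resample", seed = 4)
  r2 <- weighted_training_set(pub, priv, "2:5", mode = "resample", seed = 4)
  expect_identical(r1$data$df, r2$data$df)
  expect_equal(nrow(r1$data$df), 12)
  expect_equal(r1$weights, rep(1, 12))
})

test_that("fallback switches to the expert exactly below the threshold", {
  stat <- hergqsar:::new_prediction(
    id = c("a", "b", "c"), call = c("inactive", "active", "inactive"),
    confidence = c(0.65, 0.9, 0.71), model = "rf", provenance = "p")
  expert <- hergqsar:::new_prediction(
    id = c("a", "b", "c"), call = c("active", "inactive", "active"),
    confidence = NA_real_, model = "expert", provenance = "alert1",
    conf_level = c("matched", "no_match", "matched"))
  out <- combine_fallback(stat, expert, 0.7)
  expect_equal(out$call, c("active", "active", "inactive"))
  expect_match(out$provenance[1], "fallback_to_expert")
  # tau = 0 reproduces the statistical model; tau > 1 the expert
  expect_equal(combine_fallback(stat, expert, 0)$call, stat$call)
  expect_equal(combine_fallback(stat, expert, 1.5)$call, expert$call)
})

test_that("most-confident consensus is permutation-invariant with active ties", {
  a <- hergqsar:::new_prediction(
    id = c("x", "y", "z"), call = c("active", "inactive", "active"),
    confidence = c(0.9, 0.6, 0.7), model = "rf", provenance = "")
  b <- hergqsar:::new_prediction(
    id = c("x", "y", "z"), call = c("inactive", "inactive", "inactive"),
    confidence = c(0.6, 0.8, 0.7), model = "sohn", provenance = "")
  out <- combine_most_confident(list(a, b))
  expect_equal(out$call, c("active", "inactive", "active"))
  expect_equal(out$confidence, c(0.9, 0.8, 0.7))
  # z: tie with conflicting calls resolves to active
  out_rev <- combine_most_confident(list(b, a))
  expect_equal(out$call, out_rev$call)
  expect_equal(out$confidence, out_rev$confidence)
  expect_equal(combine_most_confident(list(a))$call, a$call)
  expect_error(combine_most_confident(list()), "at least one")
})

test_that("the full stack defers to the expert only under low consensus confidence", {
  ms <- toy_labelled_molset()
  sohn <- sohn_train(ms, min_support = 2)
  rf <- train_rf(ms, num_trees = 80, seed = 2)
  alerts <- load_alerts()
  consensus <- combine_most_confident(list(predict(sohn, ms),
                                           predict(rf, ms)))
  expert <- expert_predict(alerts, ms)
  full <- full_stack_predict(sohn, rf, alerts, ms, tau = 0.7)
  hi <- consensus$confidence >= 0.7
  expect_true(any(hi))
  expect_equal(full$call[hi], consensus$call[hi])
  expect_equal(full$call[!hi], expert$call[match(full$id, expert$id)][!hi])
  # degenerate bound: tau > 1 always uses the expert call
  full_expert <- full_stack_predict(sohn, rf, alerts, ms, tau = 1.5)
  expect_equal(full_expert$call, expert$call[match(full_expert$id, expert$id)])
})
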