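# SOHN: hypothesis selection, network construction, local kNN, confidence.

test_that("a perfectly separating feature is selected at the root", {
  ms <- toy_labelled_molset()
  model <- sohn_train(ms, min_support = 3)
  root <- model$hypotheses[model$hypotheses$depth == 0, ]
  expect_equal(nrow(root), 1)
  # the root split must be one of the amine side-chain pairs present in
  # every active and no inactive
  X <- atom_pair_incidence(ms)
  sup <- which(X[, root$feature])
  expect_setequal(ms$df$id[sup], sprintf("m%02d", 1:6))
})

test_that("degenerate training sets yield an empty hypothesis list", {
  ms <- toy_labelled_molset()
  pure <- subset_mol_set(ms, 1:6)  # single class
  m1 <- sohn_train(pure, min_support = 3)
  expect_equal(nrow(m1$hypotheses), 0)
  # min_support beyond n blocks every split
  m2 <- sohn_train(ms, min_support = nrow(ms$df) + 1L)
  expect_equal(nrow(m2$hypotheses), 0)
  # prediction falls back to global kNN with an out-of-domain flag
  p <- predict(m2, subset_mol_set(ms, 1:2))
  expect_prediction_frame(p, 2)
  expect_true(all(grepl("out_of_domain", p$provenance)))
})

test_that("the root split equals an exhaustive information-gain scan", {
  ms <- toy_labelled_molset()
  X <- atom_pair_incidence(ms)
  y01 <- as.integer(ms$df$call == "active")
  w <- rep(1, nrow(ms$df))
  model <- sohn_train(ms, min_support = 3)
  oracle <- oracle_best_root_feature(X, y01, w, min_support = 3)
  root <- model$hypotheses$feature[model$hypotheses$depth == 0]
  # tie-break order: gain desc, support desc, code asc — both sides use it
  expect_equal(root, oracle)
})

test_that("the hypothesis network is a transitively reduced inclusion order", {
  # hand-built supports: h1 > h2 > h3 chain plus a disjoint h4
  net <- build_network(
    features = c("f1", "f2", "f3", "f4"),
    supports = list(1:8, 1:4, 1:2, 9:12))
  expect_equal(nrow(net$edges), 2)
  expect_equal(unname(net$edges[, "parent"]), c(1, 2))
  expect_equal(unname(net$edges[, "child"]), c(2, 3))
  # equal supports merge into one node keeping both features
  net2 <- build_network(c("fa", "fb"), list(c(1, 2, 3), c(3, 2, 1)))
  expect_length(net2$node_support, 1)
  expect_equal(net2$node_features[[1]], c("fa", "fb"))
  # disjoint supports: two roots, no edges
  net3 <- build_network(c("x", "y"), list(1:3, 4:6))
  expect_equal(nrow(net3$edges), 0)
})

test_that("child supports are strictly contained in parent supports after training", {
  model <- sohn_train(toy_labelled_molset(), min_support = 2)
  net <- model$network
  if (nrow(net$edges) > 0) {
    for (e in seq_len(nrow(net$edges))) {
      p <- net$node_support[[net$edges[e, "parent"]]]
      c_ <- net$node_support[[net$edges[e, "child"]]]
      expect_true(all(c_ %in% p))
      expect_lt(length(c_), length(p))
    }
  }
  succeed()
})

test_that("applicability keeps only the most specific matching hypotheses", {
  model <- list(network = build_network(
    c("general", "specific", "other"),
    list(1:10, 1:4, 20:25)))
  class(model) <- "sohn_model"
  # query matching parent and child: child only
  expect_equal(applicable_hypotheses(model, c("general", "specific")), 2L)
  # query matching only the parent
  expect_equal(applicable_hypotheses(model, "general"), 1L)
  # two incomparable nodes: both
  expect_setequal(applicable_hypotheses(model, c("specific", "other")),
                  c(2L, 3L))
  expect_length(applicable_hypotheses(model, "unseen"), 0)
})

test_that("sohn_confidence honours its anchor conditions and formula", {
  expect_equal(sohn_confidence(c(1, 0.3, 0.2),
                               c("active", "inactive", "inactive"),
                               "inactive"), 1)  # exact match
  expect_equal(sohn_confidence(c(0.4, 0.4, 0.4), rep("active", 3),
                               "active"), 1)    # unanimity
  expect_equal(sohn_confidence(c(0.9, 0.8, 0.7),
                               c("active", "active", "inactive"), "active"),
               0.8 * (2 / 3), tolerance = 1e-12)
  # monotone in similarity and agreement
  base <- sohn_confidence(c(0.5, 0.5), c("active", "inactive"), "active")
  expect_gte(sohn_confidence(c(0.7, 0.5), c("active", "inactive"), "active"),
             base)
  expect_gte(sohn_confidence(c(0.5, 0.5, 0.5),
                             c("active", "active", "inactive"), "active"),
             base)
  expect_true(all(vapply(1:20, function(i) {
    set.seed(i)
    s <- runif(5); l <- sample(c("active", "inactive"), 5, replace = TRUE)
    cc <- sohn_confidence(s, l, "active")
    cc >= 0 && cc <= 1
  }, logical(1))))
})

test_that("local kNN calls the majority with deterministic tie handling", {
  # exact-match neighbour: confidence 1
  r <- local_knn_predict(c(1, 0.2), c("inactive", "inactive"), k = 2)
  expect_equal(r$confidence, 1)
  # 2 active / 1 inactive: active with confidence < 1
  r2 <- local_knn_predict(c(0.8, 0.7, 0.6),
                          c("active", "active", "inactive"), k = 3)
  expect_equal(r2$call, "active")
  expect_lt(r2$confidence, 1)
  # label tie resolves conservatively to active
  r3 <- local_knn_predict(c(0.5, 0.5), c("active", "inactive"), k = 2)
  expect_equal(r3$call, "active")
})

test_that("prediction combines locals by maximum confidence with active ties", {
  ms <- toy_labelled_molset()
  model <- sohn_train(ms, min_support = 2)
  # training compounds predict themselves with confidence 1 (exact match)
  p <- predict(model, subset_mol_set(ms, c(1, 7)))
  expect_prediction_frame(p, 2)
  expect_equal(p$confidence, c(1, 1))
  expect_equal(p$call, c("active", "inactive"))
  # determinism of the full train+predict path
  model2 <- sohn_train(ms, min_support = 2)
  expect_equal(predict(model2, ms), predict(model, ms))
})

test_that("model persistence round-trips predictions exactly", {
  ms <- toy_labelled_molset()
  model <- sohn_train(ms, min_support = 2)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  expect_equal(predict(load_model(path), ms), predict(model, ms))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(something = 1), bad)
  expect_error(load_model(bad), "not a hergqsar model")
})

test_that("the vote combination mode is available and bounded", {
  ms <- toy_labelled_molset()
  model <- sohn_train(ms, min_support = 2, combine = "vote")
  p <- predict(model, ms)
  expect_true(all(p$confidence >= 0 & p$confidence <= 1))
})
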