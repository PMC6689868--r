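# Bioactivity binarisation, conservative merging, temporal splits.

test_that("binarisation follows the 10 uM / 50% thresholds with a strict boundary", {
  pol <- threshold_policy()
  expect_equal(binarize_measurement("IC50", 5, pol), "active")
  expect_equal(binarize_measurement("percent_inhibition_at_10uM", 60, pol),
               "active")
  # values exactly at a threshold are inactive by convention
  expect_equal(binarize_measurement("IC50", 10, pol), "inactive")
  expect_equal(binarize_measurement("percent_inhibition_at_10uM", 50, pol),
               "inactive")
  expect_equal(binarize_measurement("author_call", 1, pol), "active")
  expect_equal(binarize_measurement("author_call", 0, pol), "inactive")
  # per-kind overrides take precedence
  pol2 <- threshold_policy(per_kind_overrides = c(Ki = 1))
  expect_equal(binarize_measurement("Ki", 5, pol2), "inactive")
  expect_equal(binarize_measurement("Ki", 5, pol), "active")
  expect_error(threshold_policy(potency_threshold = -1), "positive")
})

test_that("merge_calls is a conservative join: commutative, associative, idempotent", {
  expect_equal(merge_calls(c("inactive", "active", "inactive")), "active")
  expect_equal(merge_calls(c("inactive", "inactive")), "inactive")
  expect_equal(merge_calls("active"), "active")
  expect_error(merge_calls(character(0)), "empty")
  set.seed(42)
  for (i in 1:25) {
    calls <- sample(c("active", "inactive"), sample(1:6, 1), replace = TRUE)
    expect_equal(merge_calls(calls), merge_calls(rev(calls)))
    expect_equal(merge_calls(calls), merge_calls(sample(calls)))
    expect_equal(merge_calls(c(calls, calls)), merge_calls(calls))
    split_at <- sample(seq_along(calls), 1)
    expect_equal(
      merge_calls(c(merge_calls(calls[seq_len(split_at)]),
                    if (split_at < length(calls))
                      merge_calls(calls[(split_at + 1):length(calls)]))),
      merge_calls(calls))
  }
})

test_that("replicates are averaged before binarisation (mean-first rule)", {
  pol <- threshold_policy()
  expect_equal(merge_replicates(c(40, 70), "percent_inhibition_at_10uM", pol),
               "active")   # mean 55 > 50
  expect_equal(merge_replicates(c(40, 50), "percent_inhibition_at_10uM", pol),
               "inactive") # mean 45
  expect_equal(merge_replicates(60, "percent_inhibition_at_10uM", pol),
               "active")
  expect_error(merge_replicates(numeric(0), "IC50", pol), "empty")
})

test_that("mean-first and binarise-first orders genuinely differ", {
  pol <- threshold_policy()
  vals <- c(40, 70)  # one replicate above, one below the 50% cutoff
  mean_first <- merge_replicates(vals, "percent_inhibition_at_10uM", pol)
  binarise_first <- merge_calls(vapply(
    vals, function(v) binarize_measurement("percent_inhibition_at_10uM", v,
                                           pol), character(1)))
  expect_equal(mean_first, "active")
  expect_equal(binarise_first, "active")
  vals3 <- c(20, 20, 60)
  expect_equal(merge_replicates(vals3, "percent_inhibition_at_10uM", pol),
               "inactive")  # mean 33.3
  expect_equal(merge_calls(vapply(
    vals3, function(v) binarize_measurement("percent_inhibition_at_10uM", v,
                                            pol), character(1))), "active")
})

test_that("curation produces one conservative call per compound", {
  df <- data.frame(id = c("a", "b", "c"),
                   smiles = c("CCO", "CCN", "CCC"),
                   stringsAsFactors = FALSE)
  acts <- data.frame(
    id = c("a", "a", "b", "b", "c"),
    kind = c("IC50", "IC50", "percent_inhibition_at_10uM",
             "percent_inhibition_at_10uM", "author_call"),
    value = c(50, 100, 40, 70, 1))
  ms <- curate_dataset(mol_set(df, acts), audit = TRUE)
  expect_equal(ms$df$call, c("inactive", "active", "active"))
  expect_true(nrow(attr(ms, "audit")) >= 3)
})

test_that("temporal split respects the cutoff, disjointness and uniqueness", {
  df <- data.frame(
    id = sprintf("m%d", 1:10),
    smiles = c("CCO", "CCN", "CCC", "CCCC", "CCCO", "CCCN", "CCCl",
               "CCBr", "CCF", "CCI"),
    call = "inactive",
    date = as.character(as.Date("2017-01-01") + seq(0, 90, length.out = 10)))
  ms <- mol_set(df)
  cutoff <- as.Date(df$date[7])
  sp <- temporal_split(ms, cutoff)
  expect_equal(nrow(sp$train$df), 7)
  expect_equal(nrow(sp$test$df), 3)
  expect_length(intersect(sp$train$df$id, sp$test$df$id), 0)
  expect_equal(nrow(sp$train$df) + nrow(sp$test$df), nrow(ms$df))
  # cutoff before all dates
  sp0 <- temporal_split(ms, as.Date("2016-12-31"))
  expect_equal(nrow(sp0$train$df), 0)
  expect_equal(nrow(sp0$test$df), 10)
  # duplicate canonical structure across the split is removed from test
  df_dup <- df
  df_dup$smiles[10] <- "OCC"  # same canonical structure as m1
  expect_warning(spd <- temporal_split(mol_set(df_dup), cutoff), "duplicate")
  expect_equal(nrow(spd$test$df), 2)
  expect_false("m10" %in% spd$test$df$id)
})
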