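# Closed-form expected values for the 8-compound Y = X1 AND X2 toy set:
# labels have 2 of 8 active, X1 splits them 4 / (2,2).
se_y2 <- -(0.25 * log2(0.25) + 0.75 * log2(0.75))
mi_x1_y2 <- 0.25 * log2(2) + 0.25 * log2(2 / 3) + 0.5 * log2(4 / 3)

test_that("shannon_entropy matches closed forms and guards input", {
  expect_equal(shannon_entropy(c(0, 0, 0, 0, 1, 1, 1, 1)), 1.0)
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 0.0)
  expect_equal(shannon_entropy(c(0, 0, 0, 0, 0, 0, 1, 1)), se_y2)
  expect_error(shannon_entropy(integer(0)), "no observations")
  expect_error(shannon_entropy(c(0, 2)), "labels must be binary")
})

test_that("joint MI reproduces the worked single- and multi-bit values", {
  a <- table2_fixture()$activity_sets[[1]]
  expect_equal(joint_mutual_information(a, "X1"), mi_x1_y2)
  # X3 is independent of Y
  expect_equal(joint_mutual_information(a, "X3"), 0)
  # a bit identical to the labels carries the full label entropy
  v <- a$matrix$values
  v <- cbind(v, Ybit = a$labels)
  a2 <- activity_set(bit_matrix(v), a$labels, "Y")
  expect_equal(joint_mutual_information(a2, "Ybit"),
               shannon_entropy(a$labels))
  expect_error(joint_mutual_information(a, character(0)), "empty feature set")
  expect_error(joint_mutual_information(a, "nope"), "unknown feature_id")
})

test_that("normalized MI reproduces the printed 0.38 and guards degeneracy", {
  a <- table2_fixture()$activity_sets[[1]]
  expect_equal(round(normalized_mi(a, "X1"), 2), 0.38)
  expect_equal(normalized_mi(a, "X1"), mi_x1_y2 / se_y2)
  v <- a$matrix$values
  a_perfect <- activity_set(bit_matrix(cbind(v, Ybit = a$labels)),
                            a$labels, "Y")
  expect_equal(normalized_mi(a_perfect, "Ybit"), 1.0)
  a_const <- activity_set(a$matrix, rep(1L, 8), "const")
  expect_error(normalized_mi(a_const, "X1"),
               "degenerate target: entropy of activity labels is zero")
})

test_that("AIC reproduces the three-target toy extremes", {
  coll <- table1_fixture()
  for (i in 1:3) {
    expect_identical(normalized_mi(coll$activity_sets[[i]],
                                   paste0("X", i)), 1)
    for (j in setdiff(1:3, i)) {
      expect_identical(normalized_mi(coll$activity_sets[[i]],
                                     paste0("X", j)), 0)
    }
  }
  expect_equal(average_information_content(coll, c("X1", "X2")), 2 / 3,
               tolerance = 1e-14)
})

test_that("irrelevant and anti-correlated bits leave AIC unchanged", {
  coll <- table2_fixture()
  base <- average_information_content(coll, "X1")
  expect_equal(round(base, 2), 0.38)
  expect_equal(average_information_content(coll, c("X1", "X3")), base,
               tolerance = 1e-14)
  expect_equal(average_information_content(coll, c("X1", "X4")), base,
               tolerance = 1e-14)
  # degenerate target error names the target
  a_const <- activity_set(coll$activity_sets[[1]]$matrix, rep(0L, 8), "dead")
  expect_error(average_information_content(target_collection(a_const), "X1"),
               "dead")
})

test_that("plug-in joint MI agrees with dense 2^N enumeration", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      n_feat <- sample(1:10, 1)
      a <- random_activity_set(sample(10:50, 1), n_feat)
      feats <- sample(feature_ids(a), sample(seq_len(n_feat), 1))
      expect_lt(
        abs(joint_mutual_information(a, feats) -
              brute_force_mi(a$matrix$values[, feats, drop = FALSE],
                             a$labels)),
        1e-12
      )
    }
  })
})

test_that("AIC range, monotonicity, redundancy invariance and symmetry hold", {
  withr::with_seed(202, {
    for (rep in 1:20) {
      coll <- random_collection(sample(20:60, 1), 8, k = sample(1:3, 1))
      u <- feature_ids(coll)
      a_feats <- sample(u, 3)
      b_feats <- union(a_feats, sample(u, 2))
      aic_a <- average_information_content(coll, a_feats)
      aic_b <- average_information_content(coll, b_feats)
      expect_gte(aic_a, 0); expect_lte(aic_a, 1)
      expect_lte(aic_a, aic_b + 1e-9)   # subset extension cannot decrease
      # symmetry: feature order within the set is irrelevant
      expect_identical(aic_a,
                       average_information_content(coll, rev(a_feats)))
    }
    # duplicate / negated copies change nothing
    coll <- random_collection(40, 6)
    a <- coll$activity_sets[[1]]
    v <- a$matrix$values
    v2 <- cbind(v, `fp:dup` = v[, 2], `fp:neg` = 1L - v[, 2])
    coll2 <- target_collection(activity_set(bit_matrix(v2), a$labels, "t1"))
    base <- average_information_content(coll2, c("fp:1", "fp:2", "fp:3"))
    expect_equal(average_information_content(
      coll2, c("fp:1", "fp:2", "fp:3", "fp:dup")), base, tolerance = 1e-12)
    expect_equal(average_information_content(
      coll2, c("fp:1", "fp:2", "fp:3", "fp:neg")), base, tolerance = 1e-12)
  })
})

test_that("MI is bounded by both marginal entropies", {
  withr::with_seed(303, {
    for (rep in 1:15) {
      a <- random_activity_set(sample(15:40, 1), 5)
      feats <- sample(feature_ids(a), sample(1:5, 1))
      mi <- joint_mutual_information(a, feats)
      joint_pattern_entropy <- {
        key <- apply(a$matrix$values[, feats, drop = FALSE], 1, paste,
                     collapse = "")
        p <- table(key) / length(key)
        -sum(p * log2(p))
      }
      expect_lte(mi, min(joint_pattern_entropy,
                         shannon_entropy(a$labels)) + 1e-12)
      expect_gte(mi, 0)
    }
  })
})
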