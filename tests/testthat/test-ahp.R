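test_that("principal_weights solves the eigenproblem", {
  # 2x2 reciprocal matrices are always consistent: closed form
  m <- comparison_matrix(rbind(c(1, 3), c(1 / 3, 1)), c("a", "b"))
  pw <- principal_weights(m)
  expect_equal(unname(pw$weights), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(pw$lambda_max, 2, tolerance = 1e-12)

  # all-ones matrix: symmetry forces uniform weights, lambda = n
  u <- comparison_matrix(matrix(1, 3, 3), c("a", "b", "c"))
  pw <- principal_weights(u)
  expect_equal(unname(pw$weights), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(pw$lambda_max, 3, tolerance = 1e-12)

  # inconsistent 3x3 against the independent dense eigen oracle
  m <- comparison_matrix(rbind(c(1, 2, 4), c(1 / 2, 1, 3),
                               c(1 / 4, 1 / 3, 1)), c("a", "b", "c"))
  pw <- principal_weights(m)
  or <- eigen_oracle(m)
  expect_equal(unname(pw$weights), or$weights, tolerance = 1e-8)
  expect_equal(pw$lambda_max, or$lambda_max, tolerance = 1e-8)
  # frozen values from the dense solve
  expect_equal(unname(pw$weights),
               c(0.558424543095, 0.319618263936, 0.121957192969),
               tolerance = 1e-9)
  expect_equal(pw$lambda_max, 3.01829470729, tolerance = 1e-9)
  # residual contract of the returned eigenpair
  r <- as.vector(unclass(m) %*% pw$weights) - pw$lambda_max * pw$weights
  expect_lt(sqrt(sum(r^2)) / sqrt(sum(pw$weights^2)), 1e-9)
})

test_that("consistency index and ratio follow the Saaty definitions", {
  expect_equal(consistency_index(3, 3), 0)
  expect_equal(consistency_index(3.1, 3), 0.05)
  expect_equal(consistency_index(6.3, 6), 0.06)
  expect_error(consistency_index(3, 1), "n >= 2")
  expect_error(consistency_index(2.5, 3), "below matrix order")
  # tiny negative excess clamps to zero
  expect_equal(consistency_index(3 - 1e-12, 3), 0)

  expect_equal(consistency_ratio(0, 7), 0)
  expect_equal(consistency_ratio(0.5, 2), 0)   # n <= 2: always consistent
  expect_equal(consistency_ratio(0.05, 3), 0.05 / 0.58)
  expect_error(consistency_ratio(0.05, 16), "exceeds the random-index")
  expect_error(consistency_ratio(-0.1, 3), "nonnegative")
})

test_that("screening retains exactly the CR <= 0.1 judgments and is idempotent", {
  h <- tiny_hierarchy()
  # consistent cohort: everything retained
  cohort <- generate_cohort(cohort_config(sigma_ahp = 0, sigma_swing = 0,
                                          seed = 5))
  scr <- screen_judgments(cohort)
  expect_length(scr$retained, 35L)
  expect_length(scr$rejected, 0L)
  expect_true(all(scr$reports$CR < 1e-9))

  # a maximally cyclic matrix is rejected, with its report attached
  cyc <- comparison_matrix(rbind(c(1, 9, 1 / 9), c(1 / 9, 1, 9),
                                 c(9, 1 / 9, 1)), c("a", "b", "c"))
  rep <- consistency_report(cyc)
  expect_false(rep$acceptable)
  expect_equal(rep$CR, ((eigen_oracle(cyc)$lambda_max - 3) / 2) / 0.58,
               tolerance = 1e-9)
  bad <- judgment_set("pbad", "Regulators",
                      comparison_matrix(rbind(c(1, 9), c(1 / 9, 1)),
                                        c("d1", "d2")),
                      list(swing_table("d1", c(W1.1 = 100, W1.2 = 50)),
                           swing_table("d2", c(W2.1 = 100, W2.2 = 80,
                                               W2.3 = 40))), h)
  # 2x2 always passes; use threshold 0 to force a rejection path
  mixed <- screen_judgments(list(bad), threshold = -1)
  expect_length(mixed$retained, 0L)
  expect_s3_class(mixed$rejected[[1]]$report, "consistency_report")

  # idempotence
  again <- screen_judgments(scr$retained)
  expect_equal(length(again$retained), length(scr$retained))
  expect_length(again$rejected, 0L)

  # empty input
  empty <- screen_judgments(list())
  expect_length(empty$retained, 0L)
  expect_length(empty$rejected, 0L)
})

test_that("geometric-mean aggregation is exact, reciprocal and order-invariant", {
  ids <- c("a", "b", "c")
  m1 <- consistent_matrix(setNames(c(0.5, 0.3, 0.2), ids))
  expect_equal(unclass(geometric_mean_matrix(list(m1))), unclass(m1),
               tolerance = 1e-15)

  # GM(4, 1/4) = 1
  p <- comparison_matrix(rbind(c(1, 4), c(1 / 4, 1)), c("a", "b"))
  q <- comparison_matrix(rbind(c(1, 1 / 4), c(4, 1)), c("a", "b"))
  expect_equal(geometric_mean_matrix(list(p, q))[1, 2], 1, tolerance = 1e-15)

  set.seed(31)
  ms <- replicate(3, random_reciprocal(4), simplify = FALSE)
  agg <- geometric_mean_matrix(ms)
  # brute-force log-space oracle, entry by entry
  for (i in 1:4) for (j in 1:4) {
    expect_equal(agg[i, j],
                 exp(mean(log(sapply(ms, function(m) m[i, j])))),
                 tolerance = 1e-12)
  }
  # exactly reciprocal by construction: lower triangle is bitwise 1/upper
  up <- upper.tri(agg)
  expect_identical(t(unclass(agg))[up], 1 / unclass(agg)[up])
  # permutation invariance
  expect_equal(unclass(geometric_mean_matrix(ms[c(3, 1, 2)])), unclass(agg),
               tolerance = 1e-12)
  expect_error(geometric_mean_matrix(list(p, m1)), "share order")
})

test_that("group and overall domain weights recover construction ground truth", {
  # 35 identical consistent participants: every group equals the shared eigenvector
  truth <- reference_domain_weights()
  cohort <- generate_cohort(cohort_config(sigma_ahp = 0, sigma_swing = 0,
                                          seed = 2))
  gw <- group_domain_weights(cohort, default_hierarchy())
  expect_length(gw$groups, 5L)
  for (g in gw$groups) {
    expect_equal(g$weights[names(truth)], truth, tolerance = 1e-9)
  }
  expect_equal(gw$overall$weights[names(truth)], truth, tolerance = 1e-9)
  # at sigma 0 both pooling modes coincide
  gw2 <- group_domain_weights(cohort, default_hierarchy(),
                              pooling = "groups")
  expect_equal(gw2$overall$weights, gw$overall$weights, tolerance = 1e-9)

  # removing one group's members drops it from output, with a warning when
  # the group was expected
  rest <- Filter(function(j) j$group != "Researchers", cohort)
  expect_warning(
    gw3 <- group_domain_weights(rest, default_hierarchy(),
                                expected_groups = default_groups()),
    "Researchers")
  expect_false("Researchers" %in% names(gw3$groups))
  expect_length(gw3$groups, 4L)
})

test_that("eigen machinery satisfies its invariants on random matrices", {
  set.seed(1234)
  for (rep in 1:60) {
    n <- sample(3:9, 1L)
    m <- random_reciprocal(n)
    pw <- principal_weights(m)
    expect_gte(pw$lambda_max, n - 1e-9)
    rep_c <- consistency_report(m)
    expect_gte(rep_c$CR, 0)
    or <- eigen_oracle(m)
    expect_equal(unname(pw$weights), or$weights, tolerance = 1e-8)
    # a consistent matrix built from random weights is recovered exactly
    w <- normalize_weights(runif(n, 0.05, 1))
    names(w) <- paste0("e", seq_len(n))
    cm <- consistent_matrix(w)
    pw2 <- principal_weights(cm)
    expect_equal(pw2$weights, w, tolerance = 1e-9)
    expect_equal(pw2$lambda_max, n, tolerance = 1e-9)
  }
})
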