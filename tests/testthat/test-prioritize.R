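test_that("trivial and consistent matrices are recovered exactly", {
  ones <- derive_priorities(matrix(1, 3, 3))
  expect_equal(unname(ones$weights), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(ones$lambda_max, 3, tolerance = 1e-9)
  expect_equal(ones$cr, 0, tolerance = 1e-9)

  w <- c(0.6, 0.3, 0.1)
  pr <- derive_priorities(consistent_matrix(w))
  expect_equal(unname(pr$weights), w, tolerance = 1e-10)
  expect_equal(pr$cr, 0, tolerance = 1e-9)

  m <- matrix(c(1, 2, 4, 1 / 2, 1, 2, 1 / 4, 1 / 2, 1), 3, 3, byrow = TRUE)
  for (meth in c("eigenvector", "geometric_mean")) {
    pr <- derive_priorities(m, method = meth)
    expect_equal(unname(pr$weights), c(4, 2, 1) / 7, tolerance = 1e-10)
    expect_equal(pr$cr, 0, tolerance = 1e-9)
  }
})

test_that("power iteration matches a dense eigensolver on random matrices", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:7, 1)
    a <- random_saaty_matrix(n)
    pr <- derive_priorities(a)
    ev <- eigen(a)
    k <- which.max(Re(ev$values))
    v <- Re(ev$vectors[, k])
    v <- v / sum(v)
    expect_lt(max(abs(pr$weights - v)), 1e-8)
    expect_equal(pr$lambda_max, Re(ev$values[k]), tolerance = 1e-8)
  }
})

test_that("consistency ratio follows the CI/RI definition and the 10% rule", {
  # 2x2 reciprocal matrices are always consistent
  m2 <- matrix(c(1, 7, 1 / 7, 1), 2, 2, byrow = TRUE)
  pr2 <- derive_priorities(m2)
  expect_identical(pr2$cr, 0)
  expect_true(pr2$acceptable)

  # maximally cyclic 3x3: far above the threshold
  cyc <- matrix(c(1, 9, 1 / 9, 1 / 9, 1, 9, 9, 1 / 9, 1), 3, 3, byrow = TRUE)
  pr <- derive_priorities(cyc)
  expect_gt(pr$cr, 0.10)
  expect_false(pr$acceptable)
  # cross-check lambda_max against the dense solver
  expect_equal(pr$lambda_max, max(Re(eigen(cyc)$values)), tolerance = 1e-8)
  expect_equal(pr$ci, (pr$lambda_max - 3) / 2, tolerance = 1e-12)
  expect_equal(pr$cr, pr$ci / 0.58, tolerance = 1e-12)

  expect_error(consistency_ratio(diag(11) + 0), "random-index table")
  expect_error(derive_priorities(matrix(c(1, 2, 3, 1), 2, 2)), "reciprocal")
})

test_that("lambda_max >= n with equality iff consistent", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(3:6, 1)
    a <- random_saaty_matrix(n)
    pr <- derive_priorities(a)
    expect_gte(pr$lambda_max, n - 1e-9)
    w <- runif(n); w <- w / sum(w)
    prc <- derive_priorities(consistent_matrix(w))
    expect_equal(prc$lambda_max, n, tolerance = 1e-9)
    expect_equal(prc$cr, 0, tolerance = 1e-9)
  }
})

test_that("weights are equivariant under row/column permutation", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    a <- random_saaty_matrix(n)
    p <- sample(n)
    for (meth in c("eigenvector", "geometric_mean")) {
      w <- derive_priorities(a, method = meth)$weights
      wp <- derive_priorities(a[p, p], method = meth)$weights
      expect_equal(unname(wp), unname(w[p]), tolerance = 1e-9)
    }
  }
})

test_that("eigenvector and geometric-mean methods agree on near-consistent matrices", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(3:6, 1)
    # well-separated base weights so rank comparisons are meaningful
    w <- 1.5^(seq_len(n)); w <- w / sum(w)
    noise <- matrix(0, n, n)
    noise[upper.tri(noise)] <- rnorm(n * (n - 1) / 2, 0, 0.1)
    noise <- noise - t(noise)
    a <- consistent_matrix(w) * exp(noise)
    we <- derive_priorities(a, method = "eigenvector")$weights
    wg <- derive_priorities(a, method = "geometric_mean")$weights
    expect_gt(stats::cor(rank(we), rank(wg)), 0.99)
  }
})

test_that("revision suggester finds a planted inconsistent entry", {
  set.seed(5)
  hits <- 0L
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    w <- 2^(seq_len(n)); w <- w / sum(w)
    a <- consistent_matrix(w)
    i <- 1L; j <- n  # plant a gross violation on a known pair
    a[i, j] <- a[i, j] / 50
    a[j, i] <- 1 / a[i, j]
    sug <- suggest_revision(a)
    expect_true(sug$revision_needed)
    # brute force: the planted pair has the largest log deviation
    wref <- derive_priorities(a)$weights
    dev <- abs(log(a * outer(1 / wref, wref)))
    expect_equal(sort(c(match(sug$i, names(wref)), match(sug$j, names(wref)))),
                 sort(arrayInd(which.max(dev * upper.tri(dev)), dim(dev))[1, ]))
    expect_true(sug$suggested %in% c(1 / (9:2), 1:9))
    # applying the suggestion must not increase CR
    a2 <- a
    a2[match(sug$i, names(wref)), match(sug$j, names(wref))] <- sug$suggested
    a2[match(sug$j, names(wref)), match(sug$i, names(wref))] <- 1 / sug$suggested
    expect_lte(derive_priorities(a2)$cr, derive_priorities(a)$cr + 1e-12)
    hits <- hits + 1L
  }
  expect_identical(hits, 20L)
})

test_that("revision on an acceptable matrix is a no-op", {
  sug <- suggest_revision(consistent_matrix(c(0.5, 0.3, 0.2)))
  expect_false(sug$revision_needed)
})
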