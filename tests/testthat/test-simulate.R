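test_that("saaty rounding is nearest in log space with ties toward 1", {
  expect_identical(round_to_saaty(1.06), 1)
  expect_identical(round_to_saaty(8.7), 9)
  # 0.12: log distance to 1/9 is |log(0.12*9)| = 0.077, to 1/8 is 0.041
  expect_identical(round_to_saaty(0.12), 1 / 8)
  expect_identical(round_to_saaty(0.112), 1 / 9)
  # sqrt(2) is exactly between 1 and 2 in log space: resolve toward 1
  expect_identical(round_to_saaty(sqrt(2)), 1)
  expect_identical(round_to_saaty(1 / sqrt(2)), 1)
  expect_error(round_to_saaty(-1), "positive")
  expect_true(all(round_to_saaty(exp(runif(100, -3, 3))) %in%
                    c(1 / (9:2), 1:9)))
})

test_that("simulated panels are deterministic under the seed", {
  spec <- paper_shaped_panel(seed = 123)
  s1 <- simulate_judgments(spec)
  s2 <- simulate_judgments(spec)
  expect_identical(s1, s2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_judgments(s1$judgments, f1)
  write_judgments(s2$judgments, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_judgments(paper_shaped_panel(seed = 124))
  expect_false(identical(s1$judgments, s3$judgments))
})

test_that("the study-shaped preset matches the original panel design", {
  sim <- simulate_judgments(paper_shaped_panel(seed = 5))
  expect_identical(nrow(sim$panel), 16L)
  expect_equal(unname(c(table(sim$panel$group)[c("technical", "clinical")])),
               c(10L, 6L))
  expect_equal(unname(c(table(sim$judgments$respondent))), rep(31L, 16L))
})

test_that("every generated matrix passes assembly validation", {
  h <- pd_fixture()
  sim <- simulate_judgments(paper_shaped_panel(seed = 31))
  for (code in unique(sim$judgments$respondent)[1:4]) {
    jd <- sim$judgments[sim$judgments$respondent == code, ]
    for (nd in internal_nodes(h)) {
      m <- assemble_matrix(jd, nd, h)
      a <- as_matrix(m)
      expect_true(all(a * t(a) == 1))
    }
  }
})

test_that("noise-free panels with scale-ratio truths are perfectly consistent", {
  h <- toy_hierarchy()
  truth <- list(goal = c(alpha = 0.8, beta = 0.2),
                alpha = c(a1 = 3 / 4, a2 = 1 / 4),
                beta = c(b1 = 4 / 7, b2 = 2 / 7, b3 = 1 / 7))
  sim <- simulate_judgments(panel_spec(h, truth, 2, 2, sigma = 0, delta = 0,
                                       seed = 1))
  pr <- analyze_panel(h, sim$judgments, sim$panel)
  expect_lt(max(pr$consistency$cr), 1e-12)
  expect_true(all(pr$consistency$acceptable))
})

test_that("the pipeline recovers preset truths within tolerance", {
  h <- pd_fixture()
  spec <- paper_shaped_panel(seed = 42, sigma = 0.1, delta = 0)
  sim <- simulate_judgments(spec)
  pr <- suppressWarnings(analyze_panel(h, sim$judgments, sim$panel))
  for (nd in internal_nodes(h)) {
    truth <- spec$truth[[nd]][names(pr$group$local[[nd]])]
    expect_lt(mean(abs(pr$group$local[[nd]] - truth)), 0.05)
  }
})

test_that("ground-truth GW rank order is recovered exactly at low noise", {
  h <- pd_fixture()
  tr <- separated_truths(h)
  gw_true <- propagate_global_weights(h, tr)
  truth_order <- rank_needs(gw_true)$need
  for (sd in 1:50) {
    sim <- simulate_judgments(panel_spec(h, tr, 10, 6, sigma = 0.05,
                                         delta = 0, seed = sd))
    pr <- suppressWarnings(analyze_panel(h, sim$judgments, sim$panel))
    expect_identical(rank_needs(pr$group$gw)$need, truth_order)
  }
})

test_that("separated truths are a fixed point of the noise-free pipeline", {
  h <- pd_fixture()
  tr <- separated_truths(h)
  sim <- simulate_judgments(panel_spec(h, tr, 1, 0, sigma = 0, delta = 0,
                                       seed = 1))
  pr <- analyze_panel(h, sim$judgments, sim$panel)
  expect_equal(pr$group$gw, propagate_global_weights(h, tr), tolerance = 1e-10)
})

test_that("with no divergence the subgroup medians converge for large panels", {
  h <- toy_hierarchy()
  truth <- list(goal = c(alpha = 0.75, beta = 0.25),
                alpha = c(a1 = 2 / 3, a2 = 1 / 3),
                beta = c(b1 = 4 / 7, b2 = 2 / 7, b3 = 1 / 7))
  sim <- simulate_judgments(panel_spec(h, truth, 200, 200, sigma = 0.3,
                                       delta = 0, seed = 77))
  pr <- suppressWarnings(analyze_panel(h, sim$judgments, sim$panel))
  tech <- subgroup_median_weights(pr, "technical")$gw
  clin <- subgroup_median_weights(pr, "clinical")$gw
  expect_lt(max(abs(tech - clin)), 0.02)
})

test_that("panel specs validate their fields", {
  h <- toy_hierarchy()
  truth <- list(goal = c(alpha = 0.75, beta = 0.25),
                alpha = c(a1 = 2 / 3, a2 = 1 / 3),
                beta = c(b1 = 4 / 7, b2 = 2 / 7, b3 = 1 / 7))
  expect_error(panel_spec(h, truth[-1]), "missing ground-truth")
  bad <- truth; bad$goal <- c(alpha = 0.9, beta = 0.2)
  expect_error(panel_spec(h, bad), "normalized")
  expect_error(panel_spec(h, truth, sigma = -1), "sigma")
})
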