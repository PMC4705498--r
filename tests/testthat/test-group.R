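test_that("consolidation is the entry-wise geometric mean", {
  h <- toy_hierarchy()
  jd <- random_judgments(h, "beta")
  m <- assemble_matrix(jd, "beta", h)
  # idempotence on identical matrices
  expect_equal(consolidate_judgments(list(m, m, m)), as_matrix(m))
  a <- consistent_matrix(c(0.5, 0.3, 0.2))
  b <- a
  a[1, 2] <- 9; a[2, 1] <- 1 / 9
  b[1, 2] <- 1; b[2, 1] <- 1
  cm <- consolidate_judgments(list(a, b))
  expect_equal(cm[1, 2], 3)            # sqrt(9 * 1)
  a[1, 2] <- 2; a[2, 1] <- 1 / 2
  b[1, 2] <- 1 / 2; b[2, 1] <- 2
  expect_equal(consolidate_judgments(list(a, b))[1, 2], 1)
  # reciprocal, unit diagonal by construction
  set.seed(21)
  ms <- replicate(5, random_saaty_matrix(4), simplify = FALSE)
  cm <- consolidate_judgments(ms)
  expect_true(all(abs(cm * t(cm) - 1) < 1e-12))
  expect_true(all(diag(cm) == 1))
  # respondent-order invariance
  expect_equal(consolidate_judgments(rev(ms)), cm)
  expect_error(consolidate_judgments(list(diag(3) + 0, diag(4) + 0)),
               "mismatched orders")
})

test_that("global weights are path products reproducing the printed table", {
  h <- pd_fixture()
  gw <- propagate_global_weights(h, ref_local())
  expect_equal(round(unname(gw["on_off_fluctuations_detection"]), 3), 0.085)
  expect_equal(round(unname(gw["increase_self_management_support"]), 3), 0.093)
  expect_equal(round(unname(gw["increase_patient_quality_of_life"]), 3), 0.063)
  expect_error(propagate_global_weights(h, ref_local()[-1]),
               "missing local weight")
  # single category with CW = 1: GW equals LW
  th <- toy_hierarchy()
  loc <- list(goal = c(alpha = 0.5, beta = 0.5),
              alpha = c(a1 = 0.8, a2 = 0.2),
              beta = c(b1 = 0.5, b2 = 0.3, b3 = 0.2))
  gw <- propagate_global_weights(th, loc)
  expect_equal(sum(gw), 1, tolerance = 1e-12)
  expect_equal(unname(gw[c("a1", "a2")]), c(0.4, 0.1))
})

test_that("ranking is descending, stable, with shared min ranks on ties", {
  rn <- rank_needs(c(x = 0.6, y = 0.4))
  expect_identical(rn$rank, c(1L, 2L))
  rn <- rank_needs(c(a = 0.25, b = 0.25, c = 0.25, d = 0.25))
  expect_identical(rn$rank, rep(1L, 4))
  expect_identical(rn$need, c("a", "b", "c", "d"))  # document order kept
  rn <- rank_needs(c(a = 0.2, b = 0.4, c = 0.2, d = 0.2))
  expect_identical(rn$need, c("b", "a", "c", "d"))
  expect_identical(rn$rank, c(1L, 2L, 2L, 2L))
  top <- rank_needs(ref_gw())
  expect_identical(top$need[1], "increase_wearability_acceptance")
  expect_equal(top$weight[1], 0.102)
})

test_that("panel analysis yields normalized weights at every level", {
  h <- pd_fixture()
  sim <- simulate_judgments(paper_shaped_panel(seed = 8))
  pr <- suppressWarnings(analyze_panel(h, sim$judgments, sim$panel))
  # per respondent and consolidated: sum CW = 1, sum GW = 1
  expect_true(all(abs(colSums(pr$gw) - 1) < 1e-9))
  expect_true(all(abs(colSums(pr$cw) - 1) < 1e-9))
  expect_equal(sum(pr$group$gw), 1, tolerance = 1e-9)
  expect_equal(sum(pr$group$cw), 1, tolerance = 1e-9)
  # per-category leaf GWs sum exactly to that category's CW
  sets <- comparison_sets(h)
  for (cat in sets[[h$root$id]]) {
    expect_equal(sum(pr$group$gw[sets[[cat]]]),
                 unname(pr$group$cw[cat]), tolerance = 1e-12)
  }
  # GW = CW x LW leaf by leaf
  for (cat in sets[[h$root$id]]) {
    for (l in sets[[cat]]) {
      expect_equal(unname(pr$group$gw[l]),
                   unname(pr$group$cw[cat] * pr$group$local[[cat]][l]),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical consistent respondents are a fixed point of aggregation", {
  h <- toy_hierarchy()
  truth <- list(goal = c(alpha = 0.75, beta = 0.25),
                alpha = c(a1 = 2 / 3, a2 = 1 / 3),
                beta = c(b1 = 4 / 7, b2 = 2 / 7, b3 = 1 / 7))
  spec <- panel_spec(h, truth, n_technical = 4, n_clinical = 0,
                     sigma = 0, delta = 0, seed = 1)
  sim <- simulate_judgments(spec)
  pr <- analyze_panel(h, sim$judgments, sim$panel)
  expect_equal(unname(pr$group$gw), unname(propagate_global_weights(h, truth)),
               tolerance = 1e-9)
  expect_true(all(abs(pr$gw - pr$gw[, 1]) < 1e-12))  # all respondents equal
})

test_that("subgroup medians match a sort-based oracle and are unnormalized", {
  h <- pd_fixture()
  sim <- simulate_judgments(paper_shaped_panel(seed = 17))
  pr <- suppressWarnings(analyze_panel(h, sim$judgments, sim$panel))
  tech <- sim$panel$code[sim$panel$group == "technical"]
  med <- subgroup_median_weights(pr, "technical")
  for (l in sample(rownames(pr$gw), 5)) {
    v <- sort(pr$gw[l, tech])  # brute-force per-element sort
    expect_equal(unname(med$gw[l]), unname((v[5] + v[6]) / 2),
                 tolerance = 1e-12)
  }
  expect_false(isTRUE(all.equal(sum(med$gw), 1)))
  expect_equal(sum(subgroup_median_weights(pr, "technical",
                                           renormalize = TRUE)$gw), 1)
  expect_error(subgroup_median_weights(pr, "martian"), "no respondents")
  # single-respondent group: that respondent's weights
  panel1 <- sim$panel
  panel1$group[panel1$code == "t01"] <- "solo"
  pr1 <- suppressWarnings(analyze_panel(h, sim$judgments, panel1))
  expect_equal(subgroup_median_weights(pr1, "solo")$gw, pr1$gw[, "t01"])
  # group of two: element-wise midpoint
  panel2 <- sim$panel
  panel2$group[panel2$code %in% c("t01", "t02")] <- "duo"
  pr2 <- suppressWarnings(analyze_panel(h, sim$judgments, panel2))
  expect_equal(subgroup_median_weights(pr2, "duo")$gw,
               (pr2$gw[, "t01"] + pr2$gw[, "t02"]) / 2)
})

test_that("CR screening can exclude violating respondents", {
  h <- pd_fixture()
  sim <- simulate_judgments(paper_shaped_panel(seed = 42, sigma = 0.45))
  expect_warning(analyze_panel(h, sim$judgments, sim$panel), "CR > 0.1")
  pr <- analyze_panel(h, sim$judgments, sim$panel, on_violation = "exclude")
  expect_gt(length(pr$excluded), 0)
  expect_equal(sum(pr$group$gw), 1, tolerance = 1e-9)
})

test_that("weight tables carry the published table shape", {
  h <- pd_fixture()
  sim <- simulate_judgments(paper_shaped_panel(seed = 2))
  pr <- suppressWarnings(analyze_panel(h, sim$judgments, sim$panel))
  wt <- weight_tables(pr)
  expect_identical(nrow(wt$needs), 17L)
  expect_identical(nrow(wt$categories), 5L)
  expect_true(all(c("gw_group", "lw_group", "gw_median_technical",
                    "gw_median_clinical") %in% names(wt$needs)))
})
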