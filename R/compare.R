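#' Spearman rank correlation with tie correction
#'
#' Rho is the Pearson correlation of the average-tied rank vectors; the
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' adequate at the panel sizes in play. An exact permutation p-value is
#' available for small untied samples (`p_method = "exact"`, enumeration,
#' n <= 8).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param p_method `"t"` (default) or `"exact"`.
#' @return list with `rho`, `p`, `n`.
#' @examples
#' ref <- pd_reference_weights()
#' spearman(ref$needs$gw_median_technical, ref$needs$gw_median_clinical)
#' @export
spearman <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("spearman needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho is undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (abs(rho) > 1 - 1e-12) rho <- sign(rho) # clamp fp noise at the endpoints
  if (p_method == "exact") {
    if (n > 8L)
      stop("exact permutation p is supported for n <= 8 (", n, " given)")
    if (anyDuplicated(x) || anyDuplicated(y))
      stop("exact permutation p requires untied data")
    perms <- permutations(n)
    obs <- abs(rho)
    stats <- apply(perms, 1L, function(p) abs(stats::cor(rx, ry[p])))
    p <- mean(stats >= obs - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p, n = n)
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance statistic with Welch-Satterthwaite degrees of freedom
#' and two-sided p (via [stats::t.test()]). Welch's variant is the default
#' for comparing expert subgroups of unequal size; the pooled-variance
#' Student test is available with `var_equal = TRUE`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance (Student) test instead.
#' @return list with `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate variance: both groups are constant")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Boxplot summary statistics
#'
#' Quartiles by linear interpolation between closest ranks
#' ([stats::quantile()] type 7, the common plotting default); whiskers
#' extend to the most extreme data points within 1.5 IQR of the box edges;
#' everything beyond is an outlier.
#'
#' @param values numeric vector, length >= 1.
#' @return list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
boxplot_stats <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = values[!inside])
}

#' Compare two respondent groups over a panel result
#'
#' Per-need Welch t-tests on the individual global and local weights,
#' per-category t-tests on the individual category weights, Spearman rank
#' correlation between the two groups' median GW vectors, and boxplot
#' summaries of the individual GWs per need and group.
#'
#' @param panel_result an [analyze_panel()] result.
#' @param groups character vector of exactly two group labels.
#' @param var_equal passed to [welch_t()].
#' @return list with data frames `needs` (`need`, `t_gw`, `p_gw`, `t_lw`,
#'   `p_lw`), `categories` (`category`, `t_cw`, `p_cw`), the `spearman`
#'   result on median GWs, and `boxplots` (per need x group row of
#'   [boxplot_stats()] fields).
#' @export
compare_groups <- function(panel_result, groups = c("technical", "clinical"),
                           var_equal = FALSE) {
  stopifnot(inherits(panel_result, "ahp_panel"), length(groups) == 2L)
  pr <- panel_result
  codes_of <- function(g) {
    cds <- pr$panel$code[pr$panel$group == g]
    cds <- setdiff(cds, pr$excluded)
    if (length(cds) < 2L)
      stop("group '", g, "' has fewer than 2 respondents")
    cds
  }
  g1 <- codes_of(groups[1L]); g2 <- codes_of(groups[2L])
  row_test <- function(m, id) {
    res <- welch_t(m[id, g1], m[id, g2], var_equal = var_equal)
    c(t = res$t, p = res$p)
  }
  lvs <- rownames(pr$gw)
  needs <- data.frame(need = lvs, stringsAsFactors = FALSE)
  tg <- t(vapply(lvs, function(l) row_test(pr$gw, l), numeric(2)))
  tl <- t(vapply(lvs, function(l) row_test(pr$lw, l), numeric(2)))
  needs$t_gw <- tg[, 1]; needs$p_gw <- tg[, 2]
  needs$t_lw <- tl[, 1]; needs$p_lw <- tl[, 2]
  cats <- rownames(pr$cw)
  tc <- t(vapply(cats, function(cc) row_test(pr$cw, cc), numeric(2)))
  categories <- data.frame(category = cats, t_cw = tc[, 1], p_cw = tc[, 2],
                           stringsAsFactors = FALSE)
  med1 <- apply(pr$gw[, g1, drop = FALSE], 1L, stats::median)
  med2 <- apply(pr$gw[, g2, drop = FALSE], 1L, stats::median)
  sp <- spearman(med1, med2)
  box_rows <- lapply(lvs, function(l) {
    do.call(rbind, lapply(list(g1, g2), function(cds) {
      b <- boxplot_stats(pr$gw[l, cds])
      data.frame(need = l,
                 group = groups[if (identical(cds, g1)) 1L else 2L],
                 median = b$median, q1 = b$q1, q3 = b$q3,
                 whisker_low = b$whisker_low, whisker_high = b$whisker_high,
                 n_outliers = length(b$outliers), stringsAsFactors = FALSE)
    }))
  })
  boxplots <- do.call(rbind, box_rows)
  rownames(needs) <- rownames(categories) <- rownames(boxplots) <- NULL
  list(needs = needs, categories = categories, spearman = sp,
       boxplots = boxplots, groups = groups)
}
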