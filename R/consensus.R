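#' Shannon entropy of a normalized weight vector
#'
#' `H = -sum w_i ln w_i`, with the `0 * log 0 = 0` convention. Natural
#' logarithm throughout, matching the diversity-index literature the group
#' consensus measure comes from.
#'
#' @param w nonnegative weights summing to 1 (checked within `tol`).
#' @param tol allowed deviation of `sum(w)` from 1.
#' @return Entropy in nats, `>= 0`.
#' @examples
#' shannon_entropy(rep(1/4, 4))  # log(4)
#' @export
shannon_entropy <- function(w, tol = 1e-6) {
  if (any(w < 0)) stop("weights must be nonnegative")
  if (abs(sum(w) - 1) > tol)
    stop("weights must sum to 1 (got ", format(sum(w)), ")")
  p <- w[w > 0]
  -sum(p * log(p))
}

#' Entropy-based group consensus of priority vectors
#'
#' The homogeneity index S of a set of respondents' priority vectors, built
#' from alpha/beta/gamma Shannon diversity: `H_alpha` is the mean of the
#' individual entropies, `H_gamma` the entropy of the panel-level aggregate
#' vector, `H_beta = max(H_gamma - H_alpha, 0)` the between-respondent
#' diversity, and
#' `S = (M - exp(H_beta)) / (M - 1)` clamped to `[0, 1]`, with
#' `M = min(n_respondents, n_criteria)` the largest value `exp(H_beta)` can
#' attain. S is 1 when all respondents' priorities are identical and 0 when
#' they are maximally distinct.
#'
#' The aggregate behind `H_gamma` is the normalized element-wise geometric
#' mean by default (the aggregation used for consolidated judgments); when
#' some criterion has weight 0 for every respondent-product (so the
#' geometric aggregate is identically 0 and cannot be normalized), the
#' panel is maximally distinct by construction and S is 0. The classical
#' pooled (arithmetic-mean) gamma aggregate is available via
#' `aggregate = "arithmetic"`.
#'
#' @param vectors matrix with one respondent per row and one criterion per
#'   column (or a list of equal-length vectors); rows must each sum to 1.
#' @param aggregate `"geometric"` (default) or `"arithmetic"` gamma-level
#'   aggregation.
#' @return list with `S`, `H_alpha`, `H_gamma`, `H_beta`, `M`, `n`.
#' @examples
#' W <- rbind(c(.5, .3, .2), c(.4, .4, .2), c(.6, .2, .2))
#' group_consensus(W)$S
#' @export
group_consensus <- function(vectors, aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  if (is.list(vectors)) {
    len <- unique(lengths(vectors))
    if (length(len) != 1L) stop("priority vectors differ in length")
    vectors <- do.call(rbind, vectors)
  }
  n <- nrow(vectors); k <- ncol(vectors)
  if (n < 2L) stop("group consensus needs at least 2 respondents")
  if (k < 2L) stop("group consensus needs at least 2 criteria")
  h_alpha <- mean(apply(vectors, 1L, shannon_entropy))
  g <- if (aggregate == "geometric") {
    apply(vectors, 2L, function(col) exp(mean(log(col))))
  } else {
    colMeans(vectors)
  }
  m <- min(n, k)
  if (sum(g) == 0) { # all-zero geometric aggregate: maximally distinct panel
    return(list(S = 0, H_alpha = h_alpha, H_gamma = NA_real_,
                H_beta = NA_real_, M = m, n = n))
  }
  h_gamma <- shannon_entropy(g / sum(g))
  h_beta <- max(h_gamma - h_alpha, 0)
  s <- (m - exp(h_beta)) / (m - 1)
  s <- min(max(s, 0), 1)
  list(S = s, H_alpha = h_alpha, H_gamma = h_gamma, H_beta = h_beta,
       M = m, n = n)
}

#' Consensus report over a whole panel
#'
#' Applies [group_consensus()] to every comparison set's local-weight
#' vectors (one row per category), to the category-weight vectors
#' ("between categories"), and to the full global-weight vectors
#' ("overall") — the shape of a published group-consensus table.
#'
#' @param panel_result an [analyze_panel()] result.
#' @param aggregate passed to [group_consensus()].
#' @return Data frame with columns `scope`, `S`, `H_alpha`, `H_gamma`,
#'   `H_beta`, `n`: one row per category, then `between_categories`, then
#'   `overall`.
#' @export
consensus_report <- function(panel_result,
                             aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(panel_result, "ahp_panel"))
  h <- panel_result$hierarchy
  sets <- comparison_sets(h)
  codes <- setdiff(colnames(panel_result$gw), panel_result$excluded)
  loc <- panel_result$local
  loc <- loc[loc$respondent %in% codes, , drop = FALSE]
  row_for <- function(scope, vectors) {
    gc <- group_consensus(vectors, aggregate = aggregate)
    data.frame(scope = scope, S = gc$S, H_alpha = gc$H_alpha,
               H_gamma = gc$H_gamma, H_beta = gc$H_beta, n = gc$n,
               stringsAsFactors = FALSE)
  }
  cats <- setdiff(names(sets), h$root$id)
  rows <- lapply(cats, function(nd) {
    vecs <- t(vapply(codes, function(code) {
      sub <- loc[loc$respondent == code & loc$node == nd, ]
      stats::setNames(sub$weight, sub$child)[sets[[nd]]]
    }, numeric(length(sets[[nd]]))))
    row_for(nd, vecs)
  })
  rows <- c(rows,
            list(row_for("between_categories",
                         t(panel_result$cw[, codes, drop = FALSE]))),
            list(row_for("overall",
                         t(panel_result$gw[, codes, drop = FALSE]))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
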