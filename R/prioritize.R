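#' Saaty's classical random-index table, orders 1..10.
#'
#' Expected consistency index of random reciprocal matrices, used to
#' normalize CI into CR. The most widely reproduced values; an alternative
#' table can be injected wherever CR is computed.
#' @export
SAATY_RI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

check_reciprocal <- function(a, tol = 1e-9) {
  n <- nrow(a)
  if (n < 2L || ncol(a) != n) stop("judgment matrix must be square, n >= 2")
  if (any(a <= 0)) stop("judgment matrix entries must be positive")
  if (any(abs(diag(a) - 1) > tol)) stop("judgment matrix diagonal must be 1")
  if (any(abs(a * t(a) - 1) > tol))
    stop("matrix is not reciprocal: a[i,j] * a[j,i] must equal 1")
  invisible(a)
}

#' Derive a priority vector from a judgment matrix
#'
#' The principal method is the right-eigenvector of the reciprocal matrix,
#' computed by power iteration from a uniform start vector (deterministic;
#' successive normalized iterates must agree within `tol`, capped at
#' `max_iter` sweeps). The alternative is the row geometric mean,
#' `w_i` proportional to `(prod_j a_ij)^(1/n)`; the two coincide exactly on
#' consistent matrices, which is the main internal cross-check. The principal
#' eigenvalue is recovered as the average of `(A w)_i / w_i`, and the
#' consistency diagnostics CI and CR are attached (see
#' [consistency_ratio()]).
#'
#' @param m an [judgment_matrix()] or a plain positive reciprocal matrix.
#' @param method `"eigenvector"` (default) or `"geometric_mean"`.
#' @param tol convergence tolerance on the max absolute change of the
#'   normalized iterate.
#' @param max_iter power-iteration cap; exceeding it is an error that reports
#'   the iteration count.
#' @param ri random-index table indexed by matrix order (see [SAATY_RI]).
#' @param cr_max acceptability threshold on CR (0.10 by convention).
#' @return An object of class `ahp_priority`: `node`, `weights` (named,
#'   summing to 1), `lambda_max`, `ci`, `cr`, `acceptable`, `method`,
#'   `iterations`.
#' @examples
#' m <- matrix(c(1, 2, 4, 1/2, 1, 2, 1/4, 1/2, 1), 3, 3, byrow = TRUE)
#' derive_priorities(m)$weights  # 4/7, 2/7, 1/7
#' @export
derive_priorities <- function(m, method = c("eigenvector", "geometric_mean"),
                              tol = 1e-12, max_iter = 10000L,
                              ri = SAATY_RI, cr_max = 0.10) {
  method <- match.arg(method)
  node <- if (inherits(m, "ahp_judgment_matrix")) m$node else NA_character_
  a <- as_matrix(m)
  check_reciprocal(a)
  n <- nrow(a)
  iters <- 0L
  if (method == "eigenvector") {
    w <- rep(1 / n, n)
    repeat {
      w1 <- drop(a %*% w)
      w1 <- w1 / sum(w1)
      iters <- iters + 1L
      if (max(abs(w1 - w)) < tol) { w <- w1; break }
      w <- w1
      if (iters >= max_iter)
        stop("power iteration did not converge after ", iters, " iterations")
    }
  } else {
    w <- exp(rowMeans(log(a)))
    w <- w / sum(w)
  }
  names(w) <- colnames(a) %||% paste0("e", seq_len(n))
  lambda_max <- mean(drop(a %*% w) / w)
  cons <- consistency_ratio(a, lambda_max, ri = ri, cr_max = cr_max)
  structure(list(node = node, weights = w, lambda_max = lambda_max,
                 ci = cons$ci, cr = cons$cr, acceptable = cons$acceptable,
                 method = method, iterations = iters),
            class = "ahp_priority")
}

#' @export
print.ahp_priority <- function(x, ...) {
  cat("AHP priorities (", x$method, ")",
      if (!is.na(x$node)) paste0(" at node '", x$node, "'"), "\n", sep = "")
  print(round(x$weights, 4))
  cat(sprintf("lambda_max = %.4f, CI = %.4f, CR = %.4f (%s)\n",
              x$lambda_max, x$ci, x$cr,
              if (x$acceptable) "acceptable" else "CR above threshold"))
  invisible(x)
}

#' Consistency index and ratio of a judgment matrix
#'
#' `CI = (lambda_max - n) / (n - 1)` and `CR = CI / RI(n)`, screened against
#' the conventional 10% threshold. Matrices of order 1 or 2 are always
#' consistent and get `CR = 0`; orders beyond the RI table (10 with
#' [SAATY_RI]) are refused explicitly rather than extrapolated.
#'
#' @param m judgment matrix (used for its order; pass `lambda_max` from
#'   [derive_priorities()], or omit it to have it computed).
#' @param lambda_max principal eigenvalue; computed if missing.
#' @inheritParams derive_priorities
#' @return list with `ci`, `cr`, `acceptable` (`CR <= cr_max`).
#' @export
consistency_ratio <- function(m, lambda_max = NULL, ri = SAATY_RI,
                              cr_max = 0.10) {
  a <- as_matrix(m)
  n <- nrow(a)
  if (n > length(ri))
    stop("matrix order ", n, " exceeds the random-index table (max ",
         length(ri), ")")
  if (is.null(lambda_max))
    lambda_max <- derive_priorities(a, ri = ri, cr_max = cr_max)$lambda_max
  if (n <= 2L) {
    ci <- 0; cr <- 0
  } else {
    ci <- (lambda_max - n) / (n - 1)
    ci <- max(ci, 0) # guard tiny negative from floating point
    cr <- ci / ri[n]
  }
  list(ci = ci, cr = cr, acceptable = cr <= cr_max)
}

#' Suggest a single-entry revision for an inconsistent matrix
#'
#' Finds the pair whose judgment deviates most, in log space, from what the
#' current eigenvector weights imply (`max |log(a_ij w_j / w_i)|`) and
#' proposes the 1-9 scale value nearest to the implied ratio `w_i / w_j`.
#' Replacing that entry moves the matrix toward consistency. On an already
#' acceptable matrix this is a no-op and returns `revision_needed = FALSE`.
#'
#' @inheritParams derive_priorities
#' @return list with `revision_needed`, and when `TRUE` also `i`, `j`
#'   (element ids), `current` and `suggested` (a 1-9 scale value, possibly a
#'   reciprocal).
#' @export
suggest_revision <- function(m, cr_max = 0.10, ri = SAATY_RI) {
  a <- as_matrix(m)
  check_reciprocal(a)
  pr <- derive_priorities(a, ri = ri, cr_max = cr_max)
  if (pr$cr <= cr_max)
    return(list(revision_needed = FALSE, cr = pr$cr))
  w <- pr$weights
  n <- nrow(a)
  dev <- abs(log(a * outer(1 / w, w)))
  dev[lower.tri(dev, diag = TRUE)] <- -Inf
  idx <- arrayInd(which.max(dev), dim(dev))
  i <- idx[1L]; j <- idx[2L]
  ids <- names(w)
  list(revision_needed = TRUE, cr = pr$cr,
       i = ids[i], j = ids[j], current = a[i, j],
       suggested = round_to_saaty(w[[i]] / w[[j]]))
}
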