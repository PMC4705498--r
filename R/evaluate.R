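#' Weighted evaluation of a candidate system against prioritized needs
#'
#' Each need carries a fulfillment score `f_i` in `[0, 1]` (canonical coarse
#' scale: 0 = not addressed, 0.5 = partially addressed, 1 = fulfilled;
#' intermediate values are allowed). The system's score is
#' `sum f_i * GW_i`, its residual `sum (1 - f_i) * GW_i`; with normalized
#' global weights the two sum to 1, so the residual reads directly as the
#' importance-weighted room for improvement. Per-need contributions and
#' residuals support gap analysis. The single aggregate score is a
#' convenience extension of the need-by-need compliance reading; the
#' per-need table is the primary output.
#'
#' @param profile named numeric vector of fulfillment scores covering every
#'   leaf in `gw` (names = need ids), or a data frame with columns
#'   `need_id` and `fulfillment`.
#' @param gw named numeric vector of normalized global weights.
#' @return An object of class `ahp_evaluation`: list with `score`,
#'   `residual` and a data frame `needs` (`need`, `fulfillment`, `gw`,
#'   `contribution`, `residual`), in gap order (descending residual, ties
#'   by GW then document order).
#' @examples
#' ref <- pd_reference_weights()
#' gw <- stats::setNames(ref$needs$gw_group, ref$needs$need_id)
#' f <- stats::setNames(rep(1, length(gw)), names(gw))
#' f[c("increase_patient_carers_knowledge", "increase_assist_care_givers",
#'     "cognitive_behavioral_assessment")] <- 0
#' f["increase_self_management_support"] <- 0.5
#' weighted_score(f, gw)
#' @export
weighted_score <- function(profile, gw) {
  if (is.data.frame(profile)) {
    if (!all(c("need_id", "fulfillment") %in% names(profile)))
      stop("profile data frame needs columns 'need_id' and 'fulfillment'")
    profile <- stats::setNames(profile$fulfillment, profile$need_id)
  }
  missing <- setdiff(names(gw), names(profile))
  if (length(missing) > 0L)
    stop("fulfillment missing for need(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(profile), names(gw))
  if (length(extra) > 0L)
    stop("fulfillment for unknown need(s): ", paste(extra, collapse = ", "))
  f <- profile[names(gw)]
  if (any(f < 0 | f > 1))
    stop("fulfillment scores must lie in [0, 1]")
  contribution <- f * gw
  residual <- (1 - f) * gw
  needs <- data.frame(need = names(gw), fulfillment = unname(f),
                      gw = unname(gw), contribution = unname(contribution),
                      residual = unname(residual), stringsAsFactors = FALSE)
  ord <- order(-needs$residual, -needs$gw, seq_len(nrow(needs)))
  needs <- needs[ord, ]
  rownames(needs) <- NULL
  structure(list(score = sum(contribution), residual = sum(residual),
                 needs = needs),
            class = "ahp_evaluation")
}

#' @export
print.ahp_evaluation <- function(x, ...) {
  cat(sprintf("Weighted system evaluation: score %.3f (residual %.3f)\n",
              x$score, x$residual))
  cat("Leading gaps:\n")
  print(utils::head(x$needs[, c("need", "fulfillment", "gw", "residual")], 5))
  invisible(x)
}

#' Rank improvement areas by residual importance
#'
#' Needs sorted by `(1 - f_i) * GW_i` descending — the weight the system is
#' leaving on the table per need — with ties broken by GW and then document
#' order.
#'
#' @param report an [weighted_score()] result.
#' @param top_k number of areas to return (default all).
#' @return The `needs` data frame of the report, truncated to `top_k` rows.
#' @export
gap_analysis <- function(report, top_k = Inf) {
  stopifnot(inherits(report, "ahp_evaluation"), top_k >= 0)
  utils::head(report$needs, top_k)
}
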