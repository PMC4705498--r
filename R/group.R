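#' Consolidate several respondents' judgment matrices into one
#'
#' Aggregation of individual judgments (AIJ): the entry-wise geometric mean
#' of the respondents' reciprocal matrices for the same node. The result is
#' reciprocal and unit-diagonal by construction (the geometric mean of
#' reciprocals is the reciprocal of the geometric mean), though its entries
#' are generally no longer on the 1-9 scale.
#'
#' @param matrices list of [judgment_matrix()] objects (or plain reciprocal
#'   matrices) for the same node, one per respondent.
#' @return A plain positive reciprocal matrix with the common dimnames,
#'   ready for [derive_priorities()].
#' @export
consolidate_judgments <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  nodes <- unique(vapply(matrices, function(m)
    if (inherits(m, "ahp_judgment_matrix")) m$node else NA_character_,
    character(1)))
  nodes <- nodes[!is.na(nodes)]
  if (length(nodes) > 1L)
    stop("matrices belong to different nodes: ", paste(nodes, collapse = ", "))
  mats <- lapply(matrices, as_matrix)
  dims <- vapply(mats, nrow, integer(1))
  if (length(unique(dims)) != 1L)
    stop("matrices have mismatched orders: ", paste(unique(dims), collapse = ", "))
  logsum <- Reduce(`+`, lapply(mats, log))
  out <- exp(logsum / length(mats))
  diag(out) <- 1
  dimnames(out) <- dimnames(mats[[1L]])
  out
}

#' Propagate local weights down the hierarchy into global weights
#'
#' The global weight of a leaf is the product of the local weights along the
#' path from the root down to it; on the canonical two-level tree this is
#' `GW(need) = CW(category) * LW(need)`. Local vectors are expected to sum
#' to 1; a tolerance of `tol` (default 0.02) is allowed so that published
#' tables rounded to 3 decimals remain admissible inputs, and the vectors
#' are used as given (never renormalized), so that printed worked examples
#' reproduce exactly.
#'
#' @param h an [hierarchy()] object.
#' @param local named list: internal node id -> named numeric vector of
#'   local weights over that node's children.
#' @param tol allowed deviation of each local vector's sum from 1.
#' @return Named numeric vector of global weights over [leaves()] in
#'   document order.
#' @examples
#' ref <- pd_reference_weights()
#' loc <- split(stats::setNames(ref$needs$lw_group, ref$needs$need_id),
#'              ref$needs$category_id)
#' loc$pd_telehealth <- stats::setNames(ref$categories$cw_group,
#'                                      ref$categories$category_id)
#' round(propagate_global_weights(pd_fixture(), loc), 3)
#' @export
propagate_global_weights <- function(h, local, tol = 0.02) {
  stopifnot(inherits(h, "ahp_hierarchy"))
  sets <- comparison_sets(h)
  missing <- setdiff(names(sets), names(local))
  if (length(missing) > 0L)
    stop("missing local weight vector for node(s): ",
         paste(missing, collapse = ", "))
  for (node in names(sets)) {
    w <- local[[node]]
    kids <- sets[[node]]
    if (!all(kids %in% names(w)))
      stop("local weights at '", node, "' must be named by its children")
    if (abs(sum(w[kids]) - 1) > tol)
      stop("local weights at '", node, "' sum to ", round(sum(w[kids]), 4),
           ", not 1 (tolerance ", tol, ")")
  }
  gw <- c()
  walk <- function(node, acc) {
    if (length(node$children) == 0L) {
      gw[[node$id]] <<- acc
      return(invisible())
    }
    w <- local[[node$id]]
    for (ch in node$children) walk(ch, acc * w[[ch$id]])
  }
  walk(h$root, 1)
  unlist(gw)[leaves(h)]
}

#' Rank needs by global weight
#'
#' Descending by weight; exact ties share the minimum rank and keep the
#' input (document) order, so the ranking is stable.
#'
#' @param gw named numeric vector of global weights.
#' @return Data frame `need`, `weight`, `rank`, ordered by rank.
#' @export
rank_needs <- function(gw) {
  ord <- order(-gw) # stable: ties keep input order
  r <- rank(-gw, ties.method = "min")
  data.frame(need = names(gw)[ord], weight = unname(gw[ord]),
             rank = unname(r[ord]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Analyze a full judgment panel
#'
#' Runs the whole pipeline: per respondent, assemble each comparison node's
#' matrix and derive local weights ([derive_priorities()]); screen every
#' matrix's consistency ratio against `cr_max`; consolidate the panel by the
#' entry-wise geometric mean of judgments (AIJ) and derive the group local,
#' category and global weights; and compute unnormalized element-wise median
#' weights per respondent group (AIP by median). `aggregation = "aip_mean"`
#' replaces the AIJ group result by the arithmetic mean of individual
#' priority vectors (renormalized), for sensitivity checks.
#'
#' @param h an [hierarchy()] object.
#' @param judgments long-format judgments (see [read_judgments()]).
#' @param panel panel data frame (`code`, `group`, ...); defaults to all
#'   respondents found in `judgments`, group `"other"`.
#' @param method priority derivation method, see [derive_priorities()].
#' @param cr_max consistency screening threshold.
#' @param on_violation `"warn"` (keep the respondent, warn) or `"exclude"`
#'   (drop every respondent with any CR above `cr_max` from the group and
#'   subgroup results).
#' @param aggregation group aggregation: `"aij"` (geometric mean of
#'   judgments, default) or `"aip_mean"`.
#' @return An object of class `ahp_panel`: list with
#'   \describe{
#'     \item{hierarchy, panel}{the inputs (panel restricted to respondents
#'       with judgments).}
#'     \item{local}{long data frame of per-respondent local weights
#'       (`respondent`, `node`, `child`, `weight`).}
#'     \item{gw}{leaves x respondents matrix of individual global weights.}
#'     \item{cw}{categories x respondents matrix of individual root-level
#'       weights.}
#'     \item{lw}{leaves x respondents matrix of each leaf's local weight
#'       within its parent.}
#'     \item{consistency}{per respondent x node: `lambda_max`, `ci`, `cr`,
#'       `acceptable`.}
#'     \item{group}{list: `local` (per node), `cw`, `gw` from the
#'       consolidated panel.}
#'     \item{excluded}{respondent codes dropped under
#'       `on_violation = "exclude"`.}
#'   }
#' @seealso [subgroup_median_weights()], [compare_groups()],
#'   [consensus_report()]
#' @export
analyze_panel <- function(h, judgments, panel = NULL,
                          method = c("eigenvector", "geometric_mean"),
                          cr_max = 0.10,
                          on_violation = c("warn", "exclude"),
                          aggregation = c("aij", "aip_mean")) {
  method <- match.arg(method)
  on_violation <- match.arg(on_violation)
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(h, "ahp_hierarchy"))
  codes <- unique(judgments$respondent)
  if (length(codes) == 0L) stop("no judgments supplied")
  if (is.null(panel))
    panel <- data.frame(code = codes, group = "other", stringsAsFactors = FALSE)
  panel <- panel[panel$code %in% codes, , drop = FALSE]
  if (!setequal(panel$code, codes))
    stop("respondent(s) without panel entry: ",
         paste(setdiff(codes, panel$code), collapse = ", "))
  sets <- comparison_sets(h)
  lvs <- leaves(h)
  cats <- sets[[h$root$id]]

  matrices <- list() # matrices[[code]][[node]]
  priors <- list()   # priors[[code]][[node]] -> ahp_priority
  cons <- list()
  for (code in codes) {
    jd <- judgments[judgments$respondent == code, , drop = FALSE]
    matrices[[code]] <- lapply(names(sets), function(nd) assemble_matrix(jd, nd, h))
    names(matrices[[code]]) <- names(sets)
    priors[[code]] <- lapply(matrices[[code]], derive_priorities,
                             method = method, cr_max = cr_max)
    cons[[code]] <- data.frame(
      respondent = code, node = names(sets),
      lambda_max = vapply(priors[[code]], `[[`, numeric(1), "lambda_max"),
      ci = vapply(priors[[code]], `[[`, numeric(1), "ci"),
      cr = vapply(priors[[code]], `[[`, numeric(1), "cr"),
      acceptable = vapply(priors[[code]], `[[`, logical(1), "acceptable"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  consistency <- do.call(rbind, cons)

  violators <- unique(consistency$respondent[!consistency$acceptable])
  excluded <- character(0)
  if (length(violators) > 0L) {
    if (on_violation == "exclude") {
      excluded <- violators
      if (length(setdiff(codes, excluded)) == 0L)
        stop("all respondents exceed CR ", cr_max, "; nothing to aggregate")
    } else {
      warning(length(violators), " respondent(s) with CR > ", cr_max, ": ",
              paste(violators, collapse = ", "))
    }
  }
  kept <- setdiff(codes, excluded)

  # per-respondent weight matrices
  local_rows <- list()
  gw <- matrix(NA_real_, length(lvs), length(codes),
               dimnames = list(lvs, codes))
  lw <- gw
  cw <- matrix(NA_real_, length(cats), length(codes),
               dimnames = list(cats, codes))
  parent_of <- rep(names(sets), lengths(sets))
  names(parent_of) <- unlist(sets, use.names = FALSE)
  for (code in codes) {
    loc <- lapply(priors[[code]], `[[`, "weights")
    gw[, code] <- propagate_global_weights(h, loc, tol = 1e-6)
    cw[, code] <- loc[[h$root$id]][cats]
    lw[, code] <- vapply(lvs, function(l) loc[[parent_of[[l]]]][[l]], numeric(1))
    local_rows[[code]] <- do.call(rbind, lapply(names(loc), function(nd)
      data.frame(respondent = code, node = nd, child = names(loc[[nd]]),
                 weight = unname(loc[[nd]]), stringsAsFactors = FALSE)))
  }

  # group result
  group_local <- if (aggregation == "aij") {
    gl <- lapply(names(sets), function(nd) {
      cm <- consolidate_judgments(lapply(kept, function(code)
        matrices[[code]][[nd]]))
      derive_priorities(cm, method = method, cr_max = cr_max)$weights
    })
    names(gl) <- names(sets)
    gl
  } else {
    gl <- lapply(names(sets), function(nd) {
      ws <- vapply(kept, function(code) priors[[code]][[nd]]$weights,
                   numeric(length(sets[[nd]])))
      m <- rowMeans(matrix(ws, nrow = length(sets[[nd]]),
                           dimnames = list(sets[[nd]], kept)))
      m / sum(m)
    })
    names(gl) <- names(sets)
    gl
  }
  group <- list(local = group_local,
                cw = group_local[[h$root$id]][cats],
                gw = propagate_global_weights(h, group_local, tol = 1e-6))

  structure(list(hierarchy = h, panel = panel,
                 local = do.call(rbind, local_rows),
                 gw = gw, lw = lw, cw = cw,
                 consistency = consistency, group = group,
                 method = method, aggregation = aggregation,
                 cr_max = cr_max, excluded = excluded),
            class = "ahp_panel")
}

#' @export
print.ahp_panel <- function(x, ...) {
  cat("AHP panel result: ", ncol(x$gw), " respondent(s), ",
      nrow(x$gw), " needs (", x$method, ", ", x$aggregation, ")\n", sep = "")
  nviol <- length(unique(x$consistency$respondent[!x$consistency$acceptable]))
  cat("  CR screening at ", x$cr_max, ": ", nviol, " respondent(s) flagged",
      if (length(x$excluded)) paste0(", ", length(x$excluded), " excluded"),
      "\n", sep = "")
  cat("Top needs (group global weights):\n")
  print(utils::head(rank_needs(x$group$gw), 5))
  invisible(x)
}

#' Element-wise median weights of one respondent group
#'
#' Aggregation of individual priorities (AIP) by the median, the form in
#' which subgroup columns are usually reported next to the consolidated
#' group result. Medians of normalized vectors need not sum to 1, and they
#' are deliberately **not** renormalized by default, to stay comparable with
#' published subgroup columns; set `renormalize = TRUE` for sum-1 vectors.
#'
#' @param panel_result an [analyze_panel()] result.
#' @param group group label to select (`"technical"`, `"clinical"`, ...).
#' @param renormalize divide each median vector by its sum.
#' @return list with `cw`, `lw`, `gw` median vectors and `n` respondents.
#' @export
subgroup_median_weights <- function(panel_result, group, renormalize = FALSE) {
  stopifnot(inherits(panel_result, "ahp_panel"))
  codes <- panel_result$panel$code[panel_result$panel$group == group]
  codes <- setdiff(codes, panel_result$excluded)
  if (length(codes) == 0L) stop("no respondents in group '", group, "'")
  med <- function(m) apply(m[, codes, drop = FALSE], 1L, stats::median)
  out <- list(cw = med(panel_result$cw), lw = med(panel_result$lw),
              gw = med(panel_result$gw), n = length(codes))
  if (renormalize) {
    out$cw <- out$cw / sum(out$cw)
    out$gw <- out$gw / sum(out$gw)
  }
  out
}

#' Table of group and subgroup weights
#'
#' Convenience reporting: one row per need with the consolidated group GW
#' (LW), the subgroup median GW (LW) per group present in the panel, and one
#' row per category with CW likewise — the shape of the published results
#' tables. Values are rounded to `digits` (3 by default, the precision of
#' the published tables); use `digits = NULL` for full precision.
#'
#' @param panel_result an [analyze_panel()] result.
#' @param digits rounding for the emitted tables, or `NULL`.
#' @return list of data frames `needs` and `categories`.
#' @export
weight_tables <- function(panel_result, digits = 3) {
  stopifnot(inherits(panel_result, "ahp_panel"))
  h <- panel_result$hierarchy
  lvs <- leaves(h)
  cats <- comparison_sets(h)[[h$root$id]]
  rnd <- function(x) if (is.null(digits)) x else round(x, digits)
  needs <- data.frame(need = lvs,
                      gw_group = rnd(unname(panel_result$group$gw[lvs])),
                      stringsAsFactors = FALSE)
  lw_group <- local_of_leaves(panel_result$group$local, h)
  needs$lw_group <- rnd(unname(lw_group[lvs]))
  categories <- data.frame(category = cats,
                           cw_group = rnd(unname(panel_result$group$cw[cats])),
                           stringsAsFactors = FALSE)
  for (g in unique(panel_result$panel$group)) {
    sm <- subgroup_median_weights(panel_result, g)
    needs[[paste0("gw_median_", g)]] <- rnd(unname(sm$gw[lvs]))
    needs[[paste0("lw_median_", g)]] <- rnd(unname(sm$lw[lvs]))
    categories[[paste0("cw_median_", g)]] <- rnd(unname(sm$cw[cats]))
  }
  list(needs = needs, categories = categories)
}

local_of_leaves <- function(local, h) {
  sets <- comparison_sets(h)
  parent_of <- rep(names(sets), lengths(sets))
  names(parent_of) <- unlist(sets, use.names = FALSE)
  lvs <- leaves(h)
  vapply(lvs, function(l) local[[parent_of[[l]]]][[l]], numeric(1))
}
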