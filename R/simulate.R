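SAATY_VALUES <- c(1 / (9:2), 1:9)

#' Round a positive ratio to the nearest 1-9 scale value
#'
#' Nearest in log space, because the scale is multiplicative; exact ties
#' resolve toward 1 (the value closer to indifference).
#'
#' @param x positive numeric vector.
#' @return Values in `{1/9, ..., 1/2, 1, 2, ..., 9}`.
#' @examples
#' round_to_saaty(c(1.06, 8.7, 0.12))
#' @export
round_to_saaty <- function(x) {
  if (any(x <= 0)) stop("ratios must be positive")
  vapply(x, function(xi) {
    d <- abs(log(xi) - log(SAATY_VALUES))
    cand <- which(d <= min(d) + 1e-12)
    # ties toward 1: among equally close scale values pick the one nearest 1
    SAATY_VALUES[cand[which.min(abs(log(SAATY_VALUES[cand])))]]
  }, numeric(1))
}

#' Specify a synthetic expert panel
#'
#' A panel spec holds everything needed to simulate reproducible judgment
#' data: the hierarchy, one ground-truth local priority vector per
#' comparison node, log-normal judgment noise `sigma`, a subgroup divergence
#' `delta`, and the subgroup sizes. Subgroup ground truths are derived from
#' the common truth `w` as `w * exp(+/- delta/2 * d)` (renormalized), where
#' `d` is a fixed unit-norm direction per node (a centered linear ramp over
#' the node's children), so `delta` is a log-scale shift between the two
#' subgroups' views.
#'
#' @param h an [hierarchy()] object.
#' @param truth named list: comparison node id -> named local priority
#'   vector (normalized within `1e-6`).
#' @param n_technical,n_clinical respondents per subgroup (either may be 0,
#'   but not both).
#' @param sigma log-scale multiplicative noise standard deviation, >= 0.
#' @param delta log-scale divergence between the subgroup truths, >= 0.
#' @param seed integer master seed; every respondent x node matrix draws
#'   from its own derived substream, so panels are reproducible under
#'   partial regeneration.
#' @return An object of class `ahp_panel_spec`.
#' @seealso [simulate_judgments()], [paper_shaped_panel()]
#' @export
panel_spec <- function(h, truth, n_technical = 10L, n_clinical = 6L,
                       sigma = 0.15, delta = 0.1, seed = 1L) {
  stopifnot(inherits(h, "ahp_hierarchy"), sigma >= 0, delta >= 0,
            n_technical >= 0L, n_clinical >= 0L,
            n_technical + n_clinical >= 1L)
  sets <- comparison_sets(h)
  missing <- setdiff(names(sets), names(truth))
  if (length(missing) > 0L)
    stop("missing ground-truth vector for node(s): ",
         paste(missing, collapse = ", "))
  for (nd in names(sets)) {
    w <- truth[[nd]]
    if (!all(sets[[nd]] %in% names(w)))
      stop("truth at '", nd, "' must be named by its children")
    if (abs(sum(w[sets[[nd]]]) - 1) > 1e-6)
      stop("truth at '", nd, "' must be normalized")
    if (any(w <= 0)) stop("truth weights must be positive at '", nd, "'")
  }
  structure(list(hierarchy = h, truth = truth,
                 n_technical = as.integer(n_technical),
                 n_clinical = as.integer(n_clinical),
                 sigma = sigma, delta = delta, seed = as.integer(seed)),
            class = "ahp_panel_spec")
}

subgroup_truth <- function(spec, nd, group) {
  w <- spec$truth[[nd]]
  kids <- comparison_sets(spec$hierarchy)[[nd]]
  w <- w[kids]
  if (spec$delta == 0 || group == "other") return(w / sum(w))
  n <- length(w)
  d <- seq(-1, 1, length.out = n)
  d <- d / sqrt(sum(d^2))
  sgn <- if (group == "technical") 1 else -1
  w2 <- w * exp(sgn * spec$delta / 2 * d)
  w2 / sum(w2)
}

#' Simulate a panel's judgment data
#'
#' For every respondent and comparison node, each unordered pair `(i, j)`
#' receives a judgment `a_ij = round_to_saaty((w_i / w_j) * exp(e))`, with
#' `e ~ Normal(0, sigma^2)` drawn once per pair, so exact reciprocity is
#' enforced by construction; `w` is the respondent's subgroup ground truth
#' (see [panel_spec()]). With `sigma = 0` and truths whose ratios sit on the
#' 1-9 scale, every matrix is perfectly consistent. Identical specs (and
#' seeds) yield byte-identical output files.
#'
#' @param spec an [panel_spec()].
#' @return list with `panel` (respondent metadata: codes `t1..`, `c1..`) and
#'   `judgments` (long format, see [read_judgments()]).
#' @export
simulate_judgments <- function(spec) {
  stopifnot(inherits(spec, "ahp_panel_spec"))
  h <- spec$hierarchy
  sets <- comparison_sets(h)
  panel <- data.frame(
    code = c(sprintf("t%02d", seq_len(spec$n_technical)),
             sprintf("c%02d", seq_len(spec$n_clinical))),
    group = rep(c("technical", "clinical"),
                c(spec$n_technical, spec$n_clinical)),
    stringsAsFactors = FALSE)
  rows <- vector("list", nrow(panel) * length(sets))
  ri <- 0L
  for (r in seq_len(nrow(panel))) {
    for (k in seq_along(sets)) {
      nd <- names(sets)[k]
      kids <- sets[[k]]
      w <- subgroup_truth(spec, nd, panel$group[r])
      # derived substream: reproducible per respondent x node
      set.seed((spec$seed * 10007L + r * 101L + k) %% 2147483647L)
      pairs <- utils::combn(seq_along(kids), 2L)
      eps <- if (spec$sigma > 0)
        stats::rnorm(ncol(pairs), 0, spec$sigma) else numeric(ncol(pairs))
      a <- round_to_saaty(w[pairs[1L, ]] / w[pairs[2L, ]] * exp(eps))
      pref <- ifelse(a >= 1, "a", "b")
      pref[a == 1] <- "equal"
      intensity <- as.integer(round(ifelse(a >= 1, a, 1 / a)))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        respondent = panel$code[r], node = nd,
        element_a = kids[pairs[1L, ]], element_b = kids[pairs[2L, ]],
        preferred = pref, intensity = intensity, stringsAsFactors = FALSE)
    }
  }
  list(panel = panel, judgments = do.call(rbind, rows[seq_len(ri)]))
}

#' Preset: a panel shaped like the PD telehealth expert study
#'
#' The [pd_fixture()] hierarchy, 10 technical + 6 clinical respondents, and
#' ground truths taken from the published consolidated weights
#' ([pd_reference_weights()], local vectors renormalized from their
#' 3-decimal printing), with moderate judgment noise `sigma = 0.15` and a
#' mild technical/clinical divergence `delta = 0.1`.
#'
#' @param seed master seed.
#' @param sigma,delta override the preset noise and divergence.
#' @return An [panel_spec()].
#' @examples
#' sim <- simulate_judgments(paper_shaped_panel(seed = 42))
#' table(sim$panel$group)
#' @export
paper_shaped_panel <- function(seed = 1L, sigma = 0.15, delta = 0.1) {
  h <- pd_fixture()
  panel_spec(h, reference_truth(h), n_technical = 10L, n_clinical = 6L,
             sigma = sigma, delta = delta, seed = seed)
}

#' Ground-truth helpers for synthetic panels
#'
#' `reference_truth()` turns the published consolidated weights into
#' normalized local ground-truth vectors for [panel_spec()].
#' `separated_truths()` builds a deliberately *identifiable* truth profile
#' on the same tree, for parameter-recovery studies. The published profile
#' contains within-category ratios as small as 1.06, which the integer 1-9
#' instrument cannot resolve (both directions of such a pair round to 1, so
#' those weights tie for every possible respondent); recovery can therefore
#' only be asserted for truths separated beyond the instrument's
#' resolution. `separated_truths()` starts each comparison node at a
#' geometric ladder whose adjacent ratio is `min(q, 9^(1/(n-1)))` (so the
#' extreme ratio stays on the scale) and then iterates the quantized
#' derivation map — replace the truth by the eigenvector of its own
#' Saaty-rounded ratio matrix — to a fixed point. At that fixed point the
#' noise-free pipeline returns the truth exactly, so any recovery failure
#' under noise is attributable to the noise, not to quantization bias.
#'
#' @param h an [hierarchy()]; defaults to [pd_fixture()] (any tree works
#'   for `separated_truths`; `reference_truth` needs the PD ids).
#' @param q target adjacent ratio of the ladder, > 1 (capped per node by
#'   the scale's range).
#' @return named list of local truth vectors, one per comparison node.
#' @export
reference_truth <- function(h = pd_fixture()) {
  ref <- pd_reference_weights()
  truth <- lapply(split(stats::setNames(ref$needs$lw_group, ref$needs$need_id),
                        ref$needs$category_id), function(w) w / sum(w))
  cw <- stats::setNames(ref$categories$cw_group, ref$categories$category_id)
  truth[[h$root$id]] <- cw / sum(cw)
  truth
}

#' @rdname reference_truth
#' @export
separated_truths <- function(h = pd_fixture(), q = 2) {
  stopifnot(inherits(h, "ahp_hierarchy"), q > 1)
  sets <- comparison_sets(h)
  quantized_fixed_point <- function(w) {
    n <- length(w)
    for (it in seq_len(100L)) {
      a <- matrix(round_to_saaty(outer(w, 1 / w)), n, n,
                  dimnames = list(names(w), names(w)))
      diag(a) <- 1
      a[lower.tri(a)] <- 1 / t(a)[lower.tri(a)]
      w2 <- derive_priorities(a)$weights
      if (max(abs(w2 - w)) < 1e-12) return(w2)
      w <- w2
    }
    w
  }
  truth <- lapply(sets, function(kids) {
    n <- length(kids)
    r <- min(q, 9^(1 / (n - 1)))
    w <- r^((n - 1):0)
    quantized_fixed_point(stats::setNames(w / sum(w), kids))
  })
  truth
}
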