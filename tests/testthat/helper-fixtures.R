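# shared generators for the test suite; everything is built in code

# a small two-category tree: 2 + 3 needs
toy_hierarchy <- function() {
  p <- tempfile(fileext = ".yaml")
  writeLines(c(
    "goal: {id: goal, label: Toy goal}",
    "categories:",
    "- id: alpha",
    "  label: Alpha",
    "  needs:",
    "  - {id: a1, label: Need A1}",
    "  - {id: a2, label: Need A2}",
    "- id: beta",
    "  label: Beta",
    "  needs:",
    "  - {id: b1, label: Need B1}",
    "  - {id: b2, label: Need B2}",
    "  - {id: b3, label: Need B3}"), p)
  on.exit(unlink(p))
  load_hierarchy(p)
}

# random reciprocal matrix with 1-9 scale entries
random_saaty_matrix <- function(n) {
  a <- diag(n)
  vals <- c(1 / (9:2), 1:9)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a[i, j] <- sample(vals, 1)
      a[j, i] <- 1 / a[i, j]
    }
  }
  a
}

# perfectly consistent matrix from a weight vector
consistent_matrix <- function(w) outer(w, 1 / w)

# random complete judgment set for one node of a hierarchy
random_judgments <- function(h, node, respondent = "r1") {
  kids <- comparison_sets(h)[[node]]
  pairs <- utils::combn(kids, 2)
  k <- ncol(pairs)
  pref <- sample(c("a", "b", "equal"), k, replace = TRUE)
  intensity <- ifelse(pref == "equal", 1L, sample(2:9, k, replace = TRUE))
  data.frame(respondent = respondent, node = node,
             element_a = pairs[1, ], element_b = pairs[2, ],
             preferred = pref, intensity = intensity,
             stringsAsFactors = FALSE)
}

# reference weights as ready-to-use vectors / local lists
ref_gw <- function() {
  ref <- pd_reference_weights()
  stats::setNames(ref$needs$gw_group, ref$needs$need_id)
}

ref_local <- function() {
  ref <- pd_reference_weights()
  loc <- split(stats::setNames(ref$needs$lw_group, ref$needs$need_id),
               ref$needs$category_id)
  loc$pd_telehealth <- stats::setNames(ref$categories$cw_group,
                                       ref$categories$category_id)
  loc
}
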