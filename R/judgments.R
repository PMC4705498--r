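QUESTION_TEMPLATE <- paste(
  "In a technological solution for Parkinson's disease monitoring,",
  "assessment and/or management, from your point of view and according to",
  "your experience, which is the most important element and how much",
  "important it is with respect to the other? [%s] vs [%s]")

#' Generate the pairwise questionnaire for a hierarchy
#'
#' One question per unordered pair of siblings at every comparison node
#' (goal and categories), in document order. Respondents answer each
#' question by naming the more important element and an integer intensity
#' from 1 (equally important) to 9 (much more important).
#'
#' @param h an [hierarchy()] object.
#' @return A data frame with one row per question: `node`, `element_a`,
#'   `element_b` (ids in document order) and interpolated `question` text.
#' @examples
#' nrow(generate_questionnaire(pd_fixture()))  # 31
#' @export
generate_questionnaire <- function(h) {
  sets <- comparison_sets(h)
  sets <- sets[lengths(sets) >= 2L]
  rows <- lapply(names(sets), function(node) {
    kids <- sets[[node]]
    pairs <- utils::combn(kids, 2L)
    data.frame(node = node,
               element_a = pairs[1L, ], element_b = pairs[2L, ],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  labs_a <- node_label(h, out$element_a)
  labs_b <- node_label(h, out$element_b)
  out$question <- sprintf(QUESTION_TEMPLATE, labs_a, labs_b)
  rownames(out) <- NULL
  out
}

#' Reciprocal judgment matrices on the 1-9 scale
#'
#' A judgment matrix stores one respondent's pairwise comparisons at one
#' node: `a[i, j]` is the integer intensity `k` in 1..9 when element `i` is
#' preferred over `j`, and exactly `1/k` in the mirror cell. The constructor
#' keeps the integer intensities and their orientation and derives the
#' reciprocal cells, so `a[i, j] * a[j, i] == 1` holds exactly.
#'
#' @param intensity integer matrix: `intensity[i, j] = k >= 1` where row
#'   element dominates (or ties, `k = 1`); the mirror cell must be 0 (filled
#'   automatically) or the consistent reciprocal marker. Diagonal is ignored.
#' @param node id of the comparison node.
#' @param ids character vector naming the compared elements (row/col order).
#' @return An object of class `ahp_judgment_matrix`: list with `node`, `ids`,
#'   `intensity` (signed integer orientation matrix) and `a` (numeric matrix).
#' @seealso [assemble_matrix()] builds one from long-format judgments.
#' @export
judgment_matrix <- function(intensity, node = "node", ids = NULL) {
  n <- nrow(intensity)
  stopifnot(n >= 2L, ncol(intensity) == n)
  if (is.null(ids)) ids <- rownames(intensity) %||% paste0("e", seq_len(n))
  a <- matrix(1, n, n, dimnames = list(ids, ids))
  signed <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      up <- intensity[i, j]; lo <- intensity[j, i]
      if (up > 0L && lo > 0L && up > 1L && lo > 1L)
        stop("pair (", ids[i], ", ", ids[j], ") oriented both ways")
      k <- max(up, lo, 1L)
      if (k > 9L || k != round(k))
        stop("intensity for pair (", ids[i], ", ", ids[j],
             ") must be an integer in 1..9, got ", k)
      k <- as.integer(k)
      if (lo > 1L) { # j dominates i
        a[j, i] <- k; a[i, j] <- 1 / k
        signed[j, i] <- k; signed[i, j] <- -k
      } else {
        a[i, j] <- k; a[j, i] <- 1 / k
        signed[i, j] <- k; signed[j, i] <- -k
      }
    }
  }
  structure(list(node = node, ids = ids, intensity = signed, a = a),
            class = "ahp_judgment_matrix")
}

#' @export
print.ahp_judgment_matrix <- function(x, ...) {
  cat("Judgment matrix at node '", x$node, "' (", length(x$ids), " elements)\n",
      sep = "")
  print(round(x$a, 4))
  invisible(x)
}

#' @rdname judgment_matrix
#' @param m an `ahp_judgment_matrix` (or a plain positive reciprocal matrix,
#'   returned unchanged).
#' @export
as_matrix <- function(m) {
  if (inherits(m, "ahp_judgment_matrix")) return(m$a)
  if (is.matrix(m)) return(m)
  stop("not a judgment matrix")
}

#' Assemble a judgment matrix from long-format judgments
#'
#' Takes the rows of a judgments table (see [read_judgments()]) belonging to
#' one respondent and one comparison node and builds the reciprocal matrix.
#' The questionnaire instrument forces complete answers, so a missing or
#' duplicated pair is an error, named explicitly; no completion scheme for
#' partial matrices is provided.
#'
#' @param judgments data frame with columns `respondent`, `node`,
#'   `element_a`, `element_b`, `preferred` (`"a"`, `"b"` or `"equal"`),
#'   `intensity` (integer 1..9). Rows for other nodes are ignored.
#' @param node id of the comparison node to assemble.
#' @param h the [hierarchy()] the judgments refer to.
#' @return An [judgment_matrix()] over the node's children in document order.
#' @export
assemble_matrix <- function(judgments, node, h) {
  kids <- comparison_sets(h)[[node]]
  if (is.null(kids)) stop("'", node, "' is not a comparison node")
  rows <- judgments[judgments$node == node, , drop = FALSE]
  if (length(unique(rows$respondent)) > 1L)
    stop("judgments for node '", node, "' mix respondents: ",
         paste(unique(rows$respondent), collapse = ", "))
  n <- length(kids)
  intensity <- matrix(0L, n, n, dimnames = list(kids, kids))
  seen <- matrix(FALSE, n, n, dimnames = list(kids, kids))
  for (r in seq_len(nrow(rows))) {
    ea <- rows$element_a[r]; eb <- rows$element_b[r]
    if (!(ea %in% kids) || !(eb %in% kids) || ea == eb)
      stop("row ", r, ": pair (", ea, ", ", eb,
           ") is not an unordered child pair of '", node, "'")
    if (seen[ea, eb]) stop("duplicate judgment for pair (", ea, ", ", eb, ")")
    seen[ea, eb] <- seen[eb, ea] <- TRUE
    k <- rows$intensity[r]
    if (is.na(k) || k < 1 || k > 9 || k != round(k))
      stop("pair (", ea, ", ", eb, "): intensity must be an integer in 1..9, got ",
           rows$intensity[r])
    pref <- rows$preferred[r]
    if (!(pref %in% c("a", "b", "equal")))
      stop("pair (", ea, ", ", eb, "): preferred must be 'a', 'b' or 'equal'")
    if ((pref == "equal") != (k == 1))
      stop("pair (", ea, ", ", eb, "): preferred = 'equal' iff intensity = 1")
    if (pref == "b") intensity[eb, ea] <- as.integer(k)
    else intensity[ea, eb] <- as.integer(k)
  }
  miss <- which(!seen & upper.tri(seen), arr.ind = TRUE)
  if (nrow(miss) > 0L)
    stop("incomplete questionnaire at node '", node, "': missing pair (",
         kids[miss[1L, 1L]], ", ", kids[miss[1L, 2L]], ")")
  judgment_matrix(intensity, node = node, ids = kids)
}

#' Read and write judgment and panel files
#'
#' Judgments live in a long-format CSV with header
#' `respondent,node,element_a,element_b,preferred,intensity` — one row per
#' answered question. Panel metadata is a CSV
#' `code,group,sex,years_experience,years_pd,years_ehealth`; `group` must be
#' `technical`, `clinical` or `other`, and unknown values are mapped to
#' `"other"` with a warning. Both round-trip byte-stably through their
#' `write_*` counterparts.
#'
#' @param path CSV file path.
#' @param panel_path optional panel CSV; when omitted, the panel is derived
#'   from the respondent codes found in the judgments, with group `"other"`.
#' @param h optional [hierarchy()]; when given, node and element ids are
#'   validated against it.
#' @return `read_judgments` returns `list(panel = <data frame>, judgments =
#'   <data frame>)`; `read_panel` a panel data frame; the writers return
#'   `path` invisibly.
#' @export
read_judgments <- function(path, panel_path = NULL, h = NULL) {
  if (!file.exists(path)) stop("judgments file not found: ", path)
  need <- c("respondent", "node", "element_a", "element_b", "preferred",
            "intensity")
  jd <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(respondent = "character"))
  if (nrow(jd) == 0L) {
    jd <- data.frame(respondent = character(0), node = character(0),
                     element_a = character(0), element_b = character(0),
                     preferred = character(0), intensity = integer(0),
                     stringsAsFactors = FALSE)
  }
  if (!all(need %in% names(jd)))
    stop("judgments file must have columns: ", paste(need, collapse = ", "))
  jd <- jd[need]
  bad <- which(is.na(jd$intensity) | jd$intensity < 1 | jd$intensity > 9 |
                 jd$intensity != round(jd$intensity))
  if (length(bad) > 0L)
    stop("line ", bad[1L] + 1L, ": intensity must be an integer in 1..9, got ",
         jd$intensity[bad[1L]])
  if (!is.null(h)) {
    known <- node_ids(h$root)
    for (col in c("node", "element_a", "element_b")) {
      unk <- setdiff(unique(jd[[col]]), known)
      if (length(unk) > 0L)
        stop("id(s) not in hierarchy (column ", col, "): ",
             paste(unk, collapse = ", "))
    }
  }
  panel <- if (!is.null(panel_path)) {
    read_panel(panel_path)
  } else {
    data.frame(code = unique(jd$respondent),
               group = rep("other", length(unique(jd$respondent))),
               stringsAsFactors = FALSE)
  }
  list(panel = panel, judgments = jd)
}

#' @rdname read_judgments
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(code = "character"))
  if (!all(c("code", "group") %in% names(panel)))
    stop("panel file must have at least columns 'code' and 'group'")
  if (anyDuplicated(panel$code))
    stop("duplicate respondent code(s): ",
         paste(unique(panel$code[duplicated(panel$code)]), collapse = ", "))
  unknown <- !(panel$group %in% c("technical", "clinical", "other"))
  if (any(unknown)) {
    warning("unknown respondent group(s) ",
            paste(unique(panel$group[unknown]), collapse = ", "),
            " mapped to 'other'")
    panel$group[unknown] <- "other"
  }
  panel
}

#' @rdname read_judgments
#' @param judgments,panel data frames as returned by `read_judgments`.
#' @export
write_judgments <- function(judgments, path) {
  utils::write.csv(judgments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_judgments
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
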