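#' @keywords internal
new_node <- function(id, label, children = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(label), length(label) == 1L)
  structure(list(id = id, label = label, children = children),
            class = "ahp_node")
}

#' Construct and validate a decision hierarchy
#'
#' An `ahp_hierarchy` is a rooted tree: the goal at the root, categories (or
#' deeper groupings) as internal nodes, and the needs as leaves. Every
#' internal node below the root must have at least two children, because a
#' pairwise comparison of a single item is undefined; node ids must be unique
#' across the tree.
#'
#' @param root an `ahp_node` (see the `goal`/`categories` file schema in
#'   [load_hierarchy()]); typically built by [load_hierarchy()] or
#'   [pd_fixture()].
#' @return An object of class `ahp_hierarchy` with elements `root` and
#'   `depth` (number of levels below the root).
#' @seealso [load_hierarchy()], [pd_fixture()], [comparison_sets()]
#' @export
hierarchy <- function(root) {
  stopifnot(inherits(root, "ahp_node"))
  ids <- node_ids(root)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate node id(s): ", paste(unique(dup), collapse = ", "))
  # the root may hold a single category (its weight is trivially 1), but a
  # pairwise comparison below it needs at least 2 items
  check_arity <- function(node, is_root = FALSE) {
    if (!is_root && length(node$children) == 1L)
      stop("category with < 2 children: '", node$id,
           "' (a pairwise comparison needs at least 2 items)")
    for (ch in node$children) check_arity(ch)
  }
  check_arity(root, is_root = TRUE)
  structure(list(root = root, depth = tree_depth(root)),
            class = "ahp_hierarchy")
}

node_ids <- function(node) {
  c(node$id, unlist(lapply(node$children, node_ids), use.names = FALSE))
}

tree_depth <- function(node) {
  if (length(node$children) == 0L) return(0L)
  1L + max(vapply(node$children, tree_depth, integer(1)))
}

#' @export
print.ahp_hierarchy <- function(x, ...) {
  cat("AHP hierarchy: ", x$root$label, "\n", sep = "")
  cat("  ", length(internal_nodes(x)), " comparison node(s), ",
      length(leaves(x)), " leaf need(s), depth ", x$depth, "\n", sep = "")
  show <- function(node, indent) {
    for (ch in node$children) {
      cat(indent, "- ", ch$id, ": ", ch$label, "\n", sep = "")
      show(ch, paste0(indent, "  "))
    }
  }
  show(x$root, "  ")
  invisible(x)
}

#' Leaves and internal nodes of a hierarchy
#'
#' `leaves()` returns the leaf (need) ids in document order; `internal_nodes()`
#' returns the ids of all nodes that carry a pairwise comparison (the root
#' goal plus every category), also in document order. `node_label()` maps ids
#' back to their human-readable labels.
#'
#' @param h an [hierarchy()] object.
#' @param ids character vector of node ids (for `node_label`).
#' @return Character vector of ids (or labels).
#' @export
leaves <- function(h) {
  stopifnot(inherits(h, "ahp_hierarchy"))
  walk <- function(node) {
    if (length(node$children) == 0L) return(node$id)
    unlist(lapply(node$children, walk), use.names = FALSE)
  }
  walk(h$root)
}

#' @rdname leaves
#' @export
internal_nodes <- function(h) {
  stopifnot(inherits(h, "ahp_hierarchy"))
  walk <- function(node) {
    if (length(node$children) == 0L) return(character(0))
    c(node$id, unlist(lapply(node$children, walk), use.names = FALSE))
  }
  walk(h$root)
}

#' @rdname leaves
#' @export
node_label <- function(h, ids) {
  stopifnot(inherits(h, "ahp_hierarchy"))
  lab <- new.env(parent = emptyenv())
  walk <- function(node) {
    assign(node$id, node$label, envir = lab)
    lapply(node$children, walk)
  }
  walk(h$root)
  vapply(ids, function(i) {
    if (!exists(i, envir = lab)) stop("unknown node id: '", i, "'")
    get(i, envir = lab)
  }, character(1))
}

find_node <- function(h, id) {
  walk <- function(node) {
    if (node$id == id) return(node)
    for (ch in node$children) {
      hit <- walk(ch)
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  node <- walk(h$root)
  if (is.null(node)) stop("unknown node id: '", id, "'")
  node
}

#' Pairwise comparison sets of a hierarchy
#'
#' One comparison set per internal node, the root included (categories are
#' themselves compared pairwise under the goal, which is where the category
#' weights come from). Each set lists the child ids in document order.
#'
#' @param h an [hierarchy()] object.
#' @return A named list: internal node id -> character vector of child ids.
#' @examples
#' comparison_sets(pd_fixture())
#' @export
comparison_sets <- function(h) {
  stopifnot(inherits(h, "ahp_hierarchy"))
  out <- list()
  walk <- function(node) {
    if (length(node$children) == 0L) return(invisible())
    out[[node$id]] <<- vapply(node$children, `[[`, character(1), "id")
    for (ch in node$children) walk(ch)
  }
  walk(h$root)
  out
}

#' Read or write a hierarchy file
#'
#' The canonical schema is a nested mapping with a `goal` (id + label) and a
#' `categories` list; each category has `id`, `label` and a `needs` list of
#' `{id, label}` entries. A `needs` entry may itself carry a nested `needs`
#' list, so trees deeper than the canonical two levels round-trip as well.
#' YAML is the canonical format; JSON files (extension `.json`) are accepted
#' and written too.
#'
#' @param path file path; format is chosen by extension (`.json` for JSON,
#'   anything else is parsed as YAML).
#' @param h an [hierarchy()] object (for `write_hierarchy`).
#' @param format `"yaml"` or `"json"`; defaults to the extension of `path`.
#' @return `load_hierarchy` returns a validated [hierarchy()];
#'   `write_hierarchy` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' write_hierarchy(pd_fixture(), p)
#' h <- load_hierarchy(p)
#' length(leaves(h))
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) stop("hierarchy file not found: ", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  hierarchy_from_list(doc)
}

hierarchy_from_list <- function(doc) {
  if (is.null(doc$goal) || is.null(doc$categories))
    stop("hierarchy file must contain 'goal' and 'categories'")
  parse_need <- function(x) {
    if (is.null(x$id) || is.null(x$label))
      stop("every node needs 'id' and 'label' (offending entry: ",
           deparse(x, nlines = 1L), ")")
    kids <- if (!is.null(x$needs)) lapply(x$needs, parse_need) else list()
    new_node(as.character(x$id), as.character(x$label), kids)
  }
  cats <- lapply(doc$categories, parse_need)
  goal <- doc$goal
  root <- new_node(as.character(goal$id %||% "goal"),
                   as.character(goal$label %||% "Goal"), cats)
  hierarchy(root)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_hierarchy
#' @export
write_hierarchy <- function(h, path, format = c("auto", "yaml", "json")) {
  stopifnot(inherits(h, "ahp_hierarchy"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  as_list <- function(node) {
    out <- list(id = node$id, label = node$label)
    if (length(node$children) > 0L)
      out$needs <- lapply(node$children, as_list)
    out
  }
  doc <- list(goal = list(id = h$root$id, label = h$root$label),
              categories = lapply(h$root$children, as_list))
  if (format == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}
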