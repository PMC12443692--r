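#' Build an annotated suffix tree
#'
#' Constructs the suffix tree of a sentinel-terminated text with Ukkonen's
#' online algorithm (compiled code, explicit stacks throughout; no recursion
#' depth tied to the input).  Nodes are renumbered canonically by preorder
#' rank in a DFS that visits children in ascending byte order of the first
#' edge character, so node ids, traversal orders and every downstream index
#' are reproducible across runs.
#'
#' The returned object carries, per node: parent, edge span (0-based,
#' half-open into the text), string depth (total edge-label length from the
#' root), node depth (nodes on the root path), suffix link (internal
#' non-root nodes), leaf suffix index (0-based), DFS subtree interval, leaf
#' count and leaf-rank range, plus CSR child adjacency.
#'
#' @param text an [st_text], or a plain string that is passed to
#'   [st_text()] unchanged (it must already carry the sentinel).
#' @return An object of class `suffix_tree`.
#' @examples
#' tr <- build_suffix_tree(st_text("AGCATAATTTAACTAAG", append_sentinel = TRUE))
#' tr
#' @export
build_suffix_tree <- function(text) {
  if (is.character(text)) text <- st_text(text)
  if (!inherits(text, "st_text")) stop("text must be an 'st_text' (or a string)")
  core <- .build_suffix_tree_cpp(text$raw)
  tr <- c(core, list(text = text, n = text$n))
  tr$is_leaf <- as.logical(tr$is_leaf)
  # children of x sit at children_ids[(children_ptr[x]+1):children_ptr[x+1]]
  tr$children_ptr <- tr$children_ptr[-1L]
  tr$internal_ids <- which(!tr$is_leaf)
  tr$n_internal <- length(tr$internal_ids)
  tr$n_leaves <- tr$n
  # DFS-in equals the canonical id by construction; keep an explicit copy so
  # interval logic reads naturally.
  tr$dfs_in <- seq_len(tr$n_nodes)
  class(tr) <- "suffix_tree"
  stopifnot(tr$n_internal <= tr$n, tr$n_nodes == tr$n_internal + tr$n)
  tr
}

#' @export
print.suffix_tree <- function(x, ...) {
  cat(sprintf(paste0("<suffix_tree> text n = %d (sigma = %d), %d nodes: ",
                     "%d leaves + %d internal, height = %d\n"),
              x$n, x$text$sigma, x$n_nodes, x$n_leaves, x$n_internal, x$height))
  invisible(x)
}

.check_node <- function(tree, x) {
  if (!(is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x <= tree$n_nodes))
    stop("not a node id of this tree: ", deparse(substitute(x)))
  as.integer(x)
}

.check_internal <- function(tree, x) {
  x <- .check_node(tree, x)
  if (tree$is_leaf[x]) stop("node ", x, " is a leaf; an internal node is required")
  x
}

#' Suffix indexes of the leaves under a node
#'
#' @param tree a [build_suffix_tree()] result.
#' @param x node id.
#' @return Sorted integer vector of 0-based suffix indexes (the S set).
#' @export
leaves_under <- function(tree, x) {
  x <- .check_node(tree, x)
  sort(tree$leaves_by_rank[tree$first_leaf[x]:tree$last_leaf[x]])
}

#' Suffix positions under an internal node (SU set)
#'
#' `su_set(tree, x)` returns the positions in the text at which the strings
#' hanging below `x` begin, i.e. string depth of `x` plus each leaf suffix
#' index under `x`.  `s_set` returns the unshifted leaf suffix indexes.
#'
#' @param tree a `suffix_tree`.
#' @param x internal node id (the root is allowed).
#' @return Sorted integer vector, one element per leaf under `x`.
#' @export
su_set <- function(tree, x) {
  x <- .check_internal(tree, x)
  tree$depth[x] + leaves_under(tree, x)
}

#' @rdname su_set
#' @export
s_set <- function(tree, x) {
  x <- .check_internal(tree, x)
  leaves_under(tree, x)
}

#' Internal descendants of an internal node (PU set)
#'
#' All proper internal descendants of `x` in the suffix tree.  Because
#' canonical ids are preorder ranks, the subtree of `x` is the contiguous id
#' range `(x, dfs_out(x)]` and the result is a binary-searched slice of the
#' sorted internal-node list.
#'
#' @inheritParams su_set
#' @return Sorted integer vector of internal node ids (possibly empty).
#' @export
pu_set <- function(tree, x) {
  x <- .check_internal(tree, x)
  ids <- tree$internal_ids
  lo <- findInterval(x, ids) + 1L          # first internal id > x
  hi <- findInterval(tree$dfs_out[x], ids) # last internal id <= dfs_out
  if (lo > hi) integer(0) else ids[lo:hi]
}

#' Ancestor/descendant test in constant time
#'
#' Uses the canonical DFS interval: `a` lies in `b`'s subtree iff
#' `b <= a <= dfs_out(b)`.
#'
#' @param tree a `suffix_tree`.
#' @param a,b node ids.
#' @param strict if `TRUE`, `a == b` does not count.
#' @return Logical scalar: is `a` inside `b`'s subtree?
#' @export
is_descendant <- function(tree, a, b, strict = FALSE) {
  a <- .check_node(tree, a)
  b <- .check_node(tree, b)
  if (strict && a == b) return(FALSE)
  a >= b && a <= tree$dfs_out[b]
}

#' Root-path label of a node
#'
#' @inheritParams su_set
#' @param x node id (leaf or internal).
#' @return The concatenated edge labels from the root to `x` ("" for root).
#' @export
node_label <- function(tree, x) {
  x <- .check_node(tree, x)
  parts <- character(0)
  while (!is.na(tree$parent[x])) {
    parts <- c(substr(tree$text$string, tree$edge_start[x] + 1L, tree$edge_end[x]), parts)
    x <- tree$parent[x]
  }
  paste(parts, collapse = "")
}

.node_children <- function(tree, x) {
  ptr <- tree$children_ptr
  if (ptr[x + 1L] == ptr[x]) return(integer(0))
  tree$children_ids[(ptr[x] + 1L):ptr[x + 1L]]
}

#' Locate the position of a label in the tree
#'
#' Walks `label` down from the root.  If the label ends exactly at a node,
#' that node is returned with `offset = 0`; if it ends inside an edge, the
#' node *below* that edge is returned together with the number of label
#' characters still missing to reach it.  A label that does not occur in the
#' text yields `found = FALSE` rather than an error.
#'
#' @param tree a `suffix_tree`.
#' @param label non-empty string.
#' @return A list with elements `found`, `node` (id or `NA`), `offset`
#'   (0 when at the node; otherwise remaining characters on the edge) and
#'   `depth` (length of `label` when found).
#' @export
locate_node_by_label <- function(tree, label) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("label must be a non-empty string")
  txt <- tree$text$string
  m <- nchar(label)
  node <- 1L
  matched <- 0L
  while (matched < m) {
    want <- utf8ToInt(substr(label, matched + 1L, matched + 1L))
    ptr <- tree$children_ptr
    if (ptr[node + 1L] == ptr[node])
      return(list(found = FALSE, node = NA_integer_, offset = NA_integer_, depth = matched))
    idx <- (ptr[node] + 1L):ptr[node + 1L]
    hit <- idx[tree$children_char[idx] == want]
    if (length(hit) != 1L)
      return(list(found = FALSE, node = NA_integer_, offset = NA_integer_, depth = matched))
    child <- tree$children_ids[hit]
    elen <- tree$edge_end[child] - tree$edge_start[child]
    take <- min(elen, m - matched)
    edge_part <- substr(txt, tree$edge_start[child] + 1L, tree$edge_start[child] + take)
    lab_part <- substr(label, matched + 1L, matched + take)
    if (edge_part != lab_part)
      return(list(found = FALSE, node = NA_integer_, offset = NA_integer_, depth = matched))
    matched <- matched + take
    node <- child
    if (take < elen)
      return(list(found = TRUE, node = node, offset = elen - take, depth = m))
  }
  list(found = TRUE, node = node, offset = 0L, depth = m)
}

#' Internal node with an exact path label
#'
#' Convenience wrapper around [locate_node_by_label()]: returns the node id
#' whose root-path label equals `label` exactly, or `NA` when the label is
#' absent or ends mid-edge.
#'
#' @inheritParams locate_node_by_label
#' @export
node_by_label <- function(tree, label) {
  if (identical(label, "")) return(1L)
  loc <- locate_node_by_label(tree, label)
  if (loc$found && loc$offset == 0L) loc$node else NA_integer_
}

#' Debug dump of the node table
#'
#' Writes (or returns) one row per node: id, parent, edge label, string
#' depth, suffix link and leaf suffix index.
#'
#' @param tree a `suffix_tree`.
#' @param path optional TSV output path; when `NULL` the data frame is
#'   returned instead.
#' @export
st_dump <- function(tree, path = NULL) {
  ids <- seq_len(tree$n_nodes)
  edge <- ifelse(is.na(tree$edge_start), "",
                 substring(tree$text$string, tree$edge_start + 1L, tree$edge_end))
  df <- data.frame(
    node_id = ids, parent_id = tree$parent, edge_label = edge,
    depth = tree$depth, suffix_link_id = tree$suffix_link,
    suffix_index = tree$suffix_index, stringsAsFactors = FALSE)
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
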