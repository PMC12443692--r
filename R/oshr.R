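#' Build the OSHR view of a suffix tree
#'
#' The OSHR tree is the tree over the suffix tree's *internal* nodes whose
#' parent relation is the suffix link: there is an edge from `a` to `b`
#' whenever `SL(b) = a` (a reversed suffix link, i.e. an unlabeled Weiner
#' link).  Since every internal non-root node has exactly one suffix link
#' and the link drops string depth by one, the relation is acyclic and forms
#' a rooted tree with the suffix-tree root as its root.
#'
#' `SLS(x)` -- the OSHR children of `x` -- are stored in ascending order of
#' the first character of the child's path label.  Children of a common
#' OSHR parent differ in exactly that first character, so the order is total
#' and fixes the OT index permutation.
#'
#' @param tree a [build_suffix_tree()] result with suffix links (always the
#'   case for trees built by this package; a missing link raises an
#'   integrity error naming the node).
#' @return An object of class `oshr_view` with fields `sls_ptr`/`sls_ids`
#'   (CSR lists of SLS members per node), `oshr_parent`, `post_order`
#'   (whole-tree canonical post-order), `oshr_leaf` (logical per node) and
#'   `n_nodes`.
#' @examples
#' tr <- build_suffix_tree(st_text("AAAA", append_sentinel = TRUE))
#' v <- build_oshr(tr)
#' oshr_post_order(v)
#' @export
build_oshr <- function(tree) {
  stopifnot(inherits(tree, "suffix_tree"))
  internal <- tree$internal_ids
  nonroot <- internal[internal != 1L]
  sl <- tree$suffix_link[nonroot]
  if (anyNA(sl)) {
    bad <- nonroot[which(is.na(sl))[1L]]
    stop("integrity error: internal node ", bad, " has no suffix link")
  }
  # CSR of SLS lists, members ordered by first path-label character.
  ord <- order(sl, tree$path_first_char[nonroot])
  members <- nonroot[ord]
  counts <- tabulate(sl, nbins = tree$n_nodes)
  sls_ptr <- c(0L, cumsum(counts))
  oshr_parent <- rep(NA_integer_, tree$n_nodes)
  oshr_parent[nonroot] <- sl

  view <- structure(
    list(sls_ptr = sls_ptr, sls_ids = members, oshr_parent = oshr_parent,
         oshr_leaf = !tree$is_leaf & counts == 0L,
         n_nodes = tree$n_nodes, n_internal = tree$n_internal,
         tree_n = tree$n),
    class = "oshr_view")
  view$post_order <- oshr_post_order_impl(view, 1L)
  view
}

#' @export
print.oshr_view <- function(x, ...) {
  cat(sprintf("<oshr_view> %d internal nodes: %d OSHR leaves, %d OSHR internal\n",
              x$n_internal, sum(x$oshr_leaf),
              x$n_internal - sum(x$oshr_leaf)))
  invisible(x)
}

.check_view <- function(tree, view) {
  if (!inherits(view, "oshr_view")) stop("view must be an 'oshr_view'")
  if (view$n_nodes != tree$n_nodes || view$tree_n != tree$n)
    stop("integrity error: OSHR view was built from a different tree")
  invisible(TRUE)
}

#' SLS list of a node (its OSHR children)
#'
#' @param view an [build_oshr()] result.
#' @param x internal node id.
#' @return Integer vector of internal node ids whose suffix link points to
#'   `x`, in ascending order of first path-label character.
#' @export
sls <- function(view, x) {
  if (x < 1L || x > view$n_nodes) stop("not a node id: ", x)
  if (view$sls_ptr[x + 1L] == view$sls_ptr[x]) return(integer(0))
  view$sls_ids[(view$sls_ptr[x] + 1L):view$sls_ptr[x + 1L]]
}

#' Partition internal nodes into OSHR leaves and OSHR internals
#'
#' An OSHR leaf is an internal suffix-tree node with no incoming suffix
#' link (`SLS(x)` empty); all other internal nodes are OSHR internal.
#'
#' @param view an `oshr_view`.
#' @return A list with sorted id vectors `leaves` and `internals`.
#' @export
oshr_classify <- function(view) {
  list(leaves = which(view$oshr_leaf),
       internals = sort(unique(view$oshr_parent[!is.na(view$oshr_parent)])))
}

oshr_post_order_impl <- function(view, root_id) {
  # Iterative post-order; SLS children visited in stored (ascending first
  # character) order, so children precede parents and the whole order is a
  # topological order of the reversed suffix links.
  out <- integer(0)
  stack <- c(root_id)          # node stack
  state <- c(FALSE)            # FALSE = expand, TRUE = emit
  n_out <- 0L
  out <- integer(view$n_internal)
  while (length(stack) > 0L) {
    k <- length(stack)
    node <- stack[k]
    if (state[k]) {
      stack <- stack[-k]; state <- state[-k]
      n_out <- n_out + 1L
      out[n_out] <- node
    } else {
      state[k] <- TRUE
      kids <- sls(view, node)
      if (length(kids) > 0L) {
        stack <- c(stack, rev(kids))
        state <- c(state, rep(FALSE, length(kids)))
      }
    }
  }
  out[seq_len(n_out)]
}

#' Canonical post-order of the OSHR tree
#'
#' @param view an `oshr_view`.
#' @param subtree_root internal node id, or `NULL` for the whole tree.
#' @return Integer vector of internal node ids, children before parents.
#' @export
oshr_post_order <- function(view, subtree_root = NULL) {
  if (is.null(subtree_root)) return(view$post_order)
  if (subtree_root < 1L || subtree_root > view$n_nodes ||
      !(view$oshr_leaf[subtree_root] || subtree_root == 1L ||
        !is.na(view$oshr_parent[subtree_root])))
    stop("subtree_root must be an internal node of the tree")
  oshr_post_order_impl(view, as.integer(subtree_root))
}

#' OSHR ancestors of a node
#'
#' The suffix-link chain `SL(x), SL(SL(x)), ..., root`; with
#' `proper = FALSE` the chain starts at `x` itself.  Its length is bounded
#' by the suffix-tree height.
#'
#' @param view an `oshr_view`.
#' @param x internal node id.
#' @param proper drop `x` itself (default `TRUE`).
#' @return Integer vector of node ids ending at the root (empty for the
#'   root itself when `proper = TRUE`).
#' @export
oshr_ancestors <- function(view, x, proper = TRUE) {
  x <- as.integer(x)
  out <- integer(0)
  if (!proper) out <- x
  while (!is.na(view$oshr_parent[x])) {
    x <- view$oshr_parent[x]
    out <- c(out, x)
  }
  out
}

#' TSV dump of the OSHR structure
#'
#' @param view an `oshr_view`.
#' @param path optional output path; `NULL` returns the data frame.
#' @export
oshr_dump <- function(view, path = NULL) {
  internal <- view$post_order[order(view$post_order)]
  df <- data.frame(node_id = internal,
                   oshr_parent_id = view$oshr_parent[internal],
                   is_oshr_leaf = view$oshr_leaf[internal])
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
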