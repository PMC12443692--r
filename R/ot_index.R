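# OT indexing of base suffixes: a post-order traversal of the OSHR tree
# appends each node's base suffixes (ascending) to one global list; a node's
# full SU set then occupies the contiguous slice between its recorded
# Left/Right offsets, because SU(x) is the disjoint union of the base
# suffixes over x's whole OSHR subtree and children are appended first.

#' Build the OT index of base suffixes
#'
#' @inheritParams bs_oracle
#' @param table a base-suffix table from any of [bs_oracle()],
#'   [bs_algorithm1()], [bs_algorithm2()] or [bs_linear()].
#' @param subtree_root restrict indexing to the OSHR subtree rooted at this
#'   internal node; `NULL` (default) indexes the whole tree, in which case
#'   the root's offsets are `(0, n - 1)`.
#' @return An object of class `ot_suffix_index` with fields `ot_list`
#'   (0-based suffix positions in discovery order), `left`/`right`
#'   (per-node inclusive 0-based offsets, `NA` outside the indexed
#'   subtree), `covered` (logical per node) and `subtree_root`.
#' @examples
#' tr <- build_suffix_tree(st_text("AAAA", append_sentinel = TRUE))
#' v <- build_oshr(tr)
#' ot <- build_ot_suffix_index(tr, v, bs_oracle(tr, v))
#' ot$ot_list
#' @export
build_ot_suffix_index <- function(tree, view, table, subtree_root = NULL) {
  .check_view(tree, view)
  if (!inherits(table, "base_suffix_table") ||
      table$n != tree$n || table$n_nodes != tree$n_nodes)
    stop("integrity error: base-suffix table was built from a different tree")
  order <- oshr_post_order(view, subtree_root)
  left <- rep(NA_integer_, tree$n_nodes)
  right <- rep(NA_integer_, tree$n_nodes)
  ot <- integer(sum(table$counts[order]))
  pos <- 0L
  for (v in order) {
    own_left <- pos
    b <- table$bs[[v]]
    if (length(b) > 0L) {
      ot[(pos + 1L):(pos + length(b))] <- b   # already sorted ascending
      pos <- pos + length(b)
    }
    kids <- sls(view, v)
    left[v] <- if (length(kids) > 0L) left[kids[1L]] else own_left
    right[v] <- pos - 1L                      # left > right marks empty
  }
  covered <- logical(tree$n_nodes)
  covered[order] <- TRUE
  structure(
    list(ot_list = ot, left = left, right = right, covered = covered,
         subtree_root = if (is.null(subtree_root)) NA_integer_ else as.integer(subtree_root),
         n = tree$n, n_nodes = tree$n_nodes),
    class = "ot_suffix_index")
}

#' @export
print.ot_suffix_index <- function(x, ...) {
  cat(sprintf("<ot_suffix_index> %d indexed suffixes over %d covered nodes%s\n",
              length(x$ot_list), sum(x$covered),
              if (is.na(x$subtree_root)) " (whole tree)"
              else sprintf(" (OSHR subtree at node %d)", x$subtree_root)))
  invisible(x)
}

#' Reconstruct SU(x) from the OT index
#'
#' Reads the contiguous slice `ot_list[left(x)..right(x)]` -- no tree
#' descent, O(|SU(x)|).
#'
#' @param index an [build_ot_suffix_index()] result.
#' @param x internal node id covered by the index.
#' @return Sorted integer vector equal to [su_set()] of `x`.
#' @export
suffixes_under_via_ot <- function(index, x) {
  x <- as.integer(x)
  if (x < 1L || x > index$n_nodes || !index$covered[x])
    stop("node ", x, " is not covered by this OT index")
  if (index$left[x] > index$right[x]) return(integer(0))
  sort(index$ot_list[(index$left[x] + 1L):(index$right[x] + 1L)])
}

#' Exact pattern matching through the OT index
#'
#' Walks the pattern from the root of the suffix tree.  If it ends at (or
#' inside the edge above) an internal node `x`, the occurrence set is the
#' OT slice of `x` shifted back by `depth(x)`; if it ends inside a leaf
#' edge, the single occurrence is that leaf's suffix index.
#'
#' @param tree the `suffix_tree` the index was built from.
#' @param index a whole-tree [build_ot_suffix_index()] result.
#' @param pattern non-empty string.
#' @return Sorted integer vector of 0-based occurrence start positions
#'   (empty when the pattern does not occur).
#' @export
pattern_occurrences <- function(tree, index, pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a non-empty string")
  if (!is.na(index$subtree_root))
    stop("pattern matching requires a whole-tree OT index")
  loc <- locate_node_by_label(tree, pattern)
  if (!loc$found) return(integer(0))
  x <- loc$node
  if (tree$is_leaf[x]) return(tree$suffix_index[x])
  sort(suffixes_under_via_ot(index, x) - tree$depth[x])
}

#' Check every OT index invariant
#'
#' Verifies, against the tree and OSHR view, that the OT list is a
#' permutation of `0..n-1`, that the root offsets are `(0, n-1)`, that each
#' internal node's slice has `leaf_count` entries whose values equal
#' `SU(x)`, and that OSHR sibling intervals are disjoint, contiguous and
#' nested in the parent's interval with the parent's own base suffixes at
#' the tail.
#'
#' @inheritParams bs_oracle
#' @param index a whole-tree `ot_suffix_index`.
#' @return A list with `pass` (logical), `failures` (character vector) and
#'   `first_bad_node` (id of the first counterexample in canonical order,
#'   or `NA`).
#' @export
verify_ot_invariants <- function(tree, view, index) {
  .check_view(tree, view)
  failures <- character(0)
  first_bad <- NA_integer_
  note <- function(node, msg) {
    failures <<- c(failures, sprintf("node %s: %s", node, msg))
    if (is.na(first_bad)) first_bad <<- as.integer(node)
  }
  if (!setequal(index$ot_list, 0:(tree$n - 1L)) ||
      length(index$ot_list) != tree$n)
    note(1L, "ot_list is not a permutation of 0..n-1")
  if (!is.na(index$subtree_root))
    note(1L, "not a whole-tree index")
  if (index$left[1L] != 0L || index$right[1L] != tree$n - 1L)
    note(1L, "root offsets are not (0, n-1)")
  for (x in tree$internal_ids) {
    l <- index$left[x]; r <- index$right[x]
    if (is.na(l) || is.na(r)) { note(x, "missing offsets"); next }
    if (r - l + 1L != tree$leaf_count[x]) {
      note(x, "interval width != leaf count")
      next
    }
    if (!identical(sort(index$ot_list[(l + 1L):(r + 1L)]), su_set(tree, x)))
      note(x, "interval values do not reconstruct SU")
    kids <- sls(view, x)
    if (length(kids) > 0L) {
      if (index$left[x] != index$left[kids[1L]])
        note(x, "left offset != first child's left offset")
      if (length(kids) > 1L)
        for (i in 2L:length(kids))
          if (index$left[kids[i]] != index$right[kids[i - 1L]] + 1L)
            note(x, sprintf("children %d/%d intervals not contiguous",
                            kids[i - 1L], kids[i]))
      if (index$right[x] < index$right[kids[length(kids)]])
        note(x, "parent interval ends before last child's")
    }
  }
  list(pass = length(failures) == 0L, failures = failures,
       first_bad_node = first_bad)
}

#' Serialize an OT index to JSON or TSV
#'
#' @param index an `ot_suffix_index`.
#' @param path output path; extension `.json` writes the full index
#'   (`ot_list` plus per-node offsets), anything else writes a TSV of
#'   `(node_id, left, right)` for covered nodes.
#' @export
ot_serialize <- function(index, path) {
  if (grepl("\\.json$", path)) {
    ids <- which(index$covered)
    jsonlite::write_json(
      list(n = index$n, ot_list = index$ot_list,
           nodes = data.frame(node_id = ids, left = index$left[ids],
                              right = index$right[ids])),
      path, auto_unbox = TRUE)
  } else {
    ids <- which(index$covered)
    utils::write.table(
      data.frame(node_id = ids, left = index$left[ids], right = index$right[ids]),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
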