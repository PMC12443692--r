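# Base suffixes under every internal node.
#
# A suffix position s (a value of SU(x)) is *base* at x when it is not
# present in SU of any OSHR child of x.  Four interchangeable algorithms
# compute the full table; bs_oracle is the normative set-difference
# definition and the others must reproduce it exactly.

.su_raw <- function(tree, x) {
  tree$depth[x] + tree$leaves_by_rank[tree$first_leaf[x]:tree$last_leaf[x]]
}

.new_bs_table <- function(tree, bs, algorithm, ops) {
  counts <- integer(tree$n_nodes)
  counts[tree$internal_ids] <- lengths(bs[tree$internal_ids])
  structure(
    list(bs = bs, counts = counts, total = sum(counts), n = tree$n,
         n_nodes = tree$n_nodes, algorithm = algorithm, ops = ops),
    class = "base_suffix_table")
}

#' @export
print.base_suffix_table <- function(x, ...) {
  cat(sprintf("<base_suffix_table> [%s] %d base suffixes over %d internal nodes (n = %d), ops = %.0f\n",
              x$algorithm, x$total, sum(!vapply(x$bs, is.null, TRUE)), x$n,
              sum(unlist(x$ops))))
  invisible(x)
}

#' Do two base-suffix (or base-path) tables agree?
#'
#' Compares the per-node sorted sets; operation counters and algorithm
#' labels are ignored.
#'
#' @param a,b tables produced by any of the algorithms in this package.
#' @return `TRUE`, or `FALSE` with attribute `first_mismatch` (a node id).
#' @export
tables_agree <- function(a, b) {
  key <- if (inherits(a, "base_suffix_table")) "bs" else "bp"
  la <- a[[key]]; lb <- b[[key]]
  if (length(la) != length(lb)) return(structure(FALSE, first_mismatch = NA_integer_))
  for (i in seq_along(la)) {
    if (!identical(la[[i]], lb[[i]]))
      return(structure(FALSE, first_mismatch = i))
  }
  TRUE
}

#' Base suffixes by explicit set difference (ground truth)
#'
#' For each internal node `v` computes
#' `BS(v) = SU(v) - union(SU(c), c in SLS(v))` directly.  Quadratic-ish in
#' the worst case (the sum of |SU| is O(nh)) but simple enough to serve as
#' the oracle for the other three algorithms.
#'
#' @param tree a [build_suffix_tree()] result.
#' @param view the matching [build_oshr()] view.
#' @return A `base_suffix_table`: per internal node the sorted base
#'   suffixes, plus totals and operation counters.
#' @export
bs_oracle <- function(tree, view) {
  .check_view(tree, view)
  bs <- vector("list", tree$n_nodes)
  ops <- 0
  for (v in tree$internal_ids) {
    su <- .su_raw(tree, v)
    kids <- sls(view, v)
    ops <- ops + length(su)
    if (length(kids) == 0L) {
      bs[[v]] <- sort(su)
    } else {
      covered <- unlist(lapply(kids, .su_raw, tree = tree), use.names = FALSE)
      ops <- ops + length(covered)
      bs[[v]] <- sort(setdiff(su, covered))
    }
  }
  .new_bs_table(tree, bs, "oracle", list(set_elements = ops))
}

#' Base suffixes via a global membership table (post-order)
#'
#' Walks the OSHR tree in post-order keeping one global membership
#' structure `H` over suffix positions.  At node `v`, any element of
#' `SU(v)` not yet in `H` is base for `v` and is inserted.  Correctness
#' rests on the post-order: a position already in `H` can only have been
#' inserted at an OSHR descendant of `v`.  Cost is proportional to the sum
#' of |SU(v)| over internal nodes, i.e. O(nh).
#'
#' @inheritParams bs_oracle
#' @return A `base_suffix_table` identical to [bs_oracle()]'s.
#' @export
bs_algorithm1 <- function(tree, view) {
  .check_view(tree, view)
  bs <- vector("list", tree$n_nodes)
  H <- logical(tree$n)
  ops <- 0
  for (v in view$post_order) {
    su <- .su_raw(tree, v)
    ops <- ops + length(su)
    fresh <- su[!H[su + 1L]]
    H[fresh + 1L] <- TRUE
    bs[[v]] <- sort(fresh)
  }
  .new_bs_table(tree, bs, "algorithm1", list(membership_tests = ops))
}

#' Base suffixes via predecessor-leaf interval containment
#'
#' At node `v`, the suffix `depth(v) + z` (leaf `z` under `v`) is covered by
#' an OSHR child exactly when the leaf with suffix index `z - 1` lies in the
#' subtree of some member of `SLS(v)`; `z = 0` has no predecessor and is
#' always base.  The containment test binary-searches the (at most sigma)
#' sorted DFS intervals of the SLS members, giving O(nh log2 sigma).
#'
#' @inheritParams bs_oracle
#' @return A `base_suffix_table` identical to [bs_oracle()]'s.
#' @export
bs_algorithm2 <- function(tree, view) {
  .check_view(tree, view)
  bs <- vector("list", tree$n_nodes)
  ops <- 0
  for (v in tree$internal_ids) {
    zs <- tree$leaves_by_rank[tree$first_leaf[v]:tree$last_leaf[v]]
    kids <- sort(sls(view, v))       # ids are dfs_in: sorted = interval order
    ops <- ops + length(zs) * (1 + ceiling(log2(length(kids) + 1)))
    if (length(kids) == 0L) {
      bs[[v]] <- sort(tree$depth[v] + zs)
      next
    }
    rights <- tree$dfs_out[kids]
    base <- logical(length(zs))
    base[zs == 0L] <- TRUE
    nz <- which(zs > 0L)
    if (length(nz) > 0L) {
      pred_pos <- tree$leaf_id_by_suffix[zs[nz]]  # leaf with suffix z-1; id = dfs_in
      j <- findInterval(pred_pos, kids)
      covered <- j >= 1L & pred_pos <= rights[pmax(j, 1L)]
      base[nz] <- !covered
    }
    bs[[v]] <- sort(tree$depth[v] + zs[base])
  }
  .new_bs_table(tree, bs, "algorithm2", list(interval_tests = ops))
}

#' Reference leaves, reference internals and their inbetween chains
#'
#' The machinery behind the linear algorithms.  For a leaf `A` with suffix
#' index `x <= n - 2`, let `B = parent(A)`, `C` the leaf with suffix index
#' `x + 1` and `D = parent(C)`.  When `SL(B) != D` (with `SL(root)` read as
#' a virtual super-root), every ancestor of `C` that is a strict descendant
#' of `SL(B)` -- the contiguous parent chain from `D` down-to-depth
#' `depth(B)` -- is an *inbetween node* for `A`, and `A` is a *reference
#' leaf* for it.  The internal-node analogue replaces `C` by `SL(A)`.
#'
#' @inheritParams bs_oracle
#' @return An object of class `reference_annotation` holding the two record
#'   tables, their inbetween chains, and walk counters.
#' @export
find_reference_annotation <- function(tree, view) {
  .check_view(tree, view)
  par <- tree$parent
  sl <- tree$suffix_link
  dep <- tree$depth
  chain_steps <- 0L

  walk_chain <- function(D, min_depth) {
    # ancestors of C from D upward while string depth >= min_depth
    out <- integer(0)
    u <- D
    while (!is.na(u) && dep[u] >= min_depth) {
      out <- c(out, u)
      u <- par[u]
    }
    chain_steps <<- chain_steps + length(out) + 1L
    out
  }

  n <- tree$n
  # ---- reference leaves ----------------------------------------------------
  xs <- 0:(n - 2L)
  A <- tree$leaf_id_by_suffix[xs + 1L]
  B <- par[A]
  C <- tree$leaf_id_by_suffix[xs + 2L]
  D <- par[C]
  slB <- ifelse(B == 1L, -1L, sl[B])      # -1 codes the virtual super-root
  is_ref <- slB != D                      # virtual super-root never equals D
  leaf_records <- data.frame(
    suffix = xs[is_ref], A = A[is_ref], B = B[is_ref],
    C = C[is_ref], D = D[is_ref])
  min_depth <- ifelse(leaf_records$B == 1L, 0L, dep[leaf_records$B])
  leaf_chains <- vector("list", nrow(leaf_records))
  for (i in seq_len(nrow(leaf_records)))
    leaf_chains[[i]] <- walk_chain(leaf_records$D[i], min_depth[i])

  # ---- reference internals -------------------------------------------------
  Ai <- tree$internal_ids[tree$internal_ids != 1L]
  Bi <- par[Ai]
  Ci <- sl[Ai]
  Di <- par[Ci]
  slBi <- ifelse(Bi == 1L, -1L, sl[Bi])
  # depth-1 nodes have C = root: no node above C exists, hence no record
  is_refi <- (Ci != 1L) & (slBi != Di)
  internal_records <- data.frame(
    A = Ai[is_refi], B = Bi[is_refi], C = Ci[is_refi], D = Di[is_refi])
  min_depth_i <- ifelse(internal_records$B == 1L, 0L, dep[internal_records$B])
  internal_chains <- vector("list", nrow(internal_records))
  for (i in seq_len(nrow(internal_records)))
    internal_chains[[i]] <- walk_chain(internal_records$D[i], min_depth_i[i])

  structure(
    list(leaf_records = leaf_records, leaf_chains = leaf_chains,
         internal_records = internal_records, internal_chains = internal_chains,
         chain_steps = chain_steps, tree_n = tree$n, n_nodes = tree$n_nodes),
    class = "reference_annotation")
}

#' @export
print.reference_annotation <- function(x, ...) {
  cat(sprintf("<reference_annotation> %d reference leaves, %d reference internals, %d chain nodes\n",
              nrow(x$leaf_records), nrow(x$internal_records),
              sum(lengths(x$leaf_chains)) + sum(lengths(x$internal_chains))))
  invisible(x)
}

#' Base suffixes in linear time via reference nodes
#'
#' Emits every base suffix exactly once, in O(1) per suffix after the
#' reference annotation:
#' \itemize{
#'   \item the first suffix (index 0) has no predecessor, so it is base at
#'     every internal ancestor `u` of its leaf, contributing `depth(u)`;
#'   \item a reference leaf with suffix index `x` contributes
#'     `depth(u) + x + 1` at each of its inbetween nodes `u`;
#'   \item a reference internal node `A` contributes, for every leaf index
#'     `w` under `A`, the suffix `depth(u) + w + 1` at each inbetween node
#'     `u` (the leaves under `A` are read off as one contiguous slice).
#' }
#' A duplicate-emission guard backs the claim that each base suffix is
#' derived from exactly one record.
#'
#' @inheritParams bs_oracle
#' @param annotation a [find_reference_annotation()] result for the same
#'   tree.
#' @return A `base_suffix_table` identical to [bs_oracle()]'s.
#' @export
bs_linear <- function(tree, view, annotation) {
  .check_view(tree, view)
  if (!inherits(annotation, "reference_annotation") ||
      annotation$tree_n != tree$n || annotation$n_nodes != tree$n_nodes)
    stop("annotation was not built from this tree")

  n <- tree$n
  nodes <- integer(n)
  vals <- integer(n)
  k <- 0L
  emissions <- 0L
  dep <- tree$depth

  emit <- function(us, ss) {
    len <- length(ss)
    if (len == 0L) return(invisible())
    nodes[(k + 1L):(k + len)] <<- us
    vals[(k + 1L):(k + len)] <<- ss
    k <<- k + len
    invisible()
  }

  # first suffix: base at every internal ancestor of leaf 0, incl. the root
  u <- tree$parent[tree$leaf_id_by_suffix[1L]]
  while (!is.na(u)) {
    emit(u, dep[u])
    u <- tree$parent[u]
  }

  lr <- annotation$leaf_records
  for (i in seq_len(nrow(lr))) {
    chain <- annotation$leaf_chains[[i]]
    emit(chain, dep[chain] + lr$suffix[i] + 1L)
  }

  ir <- annotation$internal_records
  for (i in seq_len(nrow(ir))) {
    chain <- annotation$internal_chains[[i]]
    A <- ir$A[i]
    ws <- tree$leaves_by_rank[tree$first_leaf[A]:tree$last_leaf[A]]
    for (u in chain) emit(u, dep[u] + ws + 1L)
  }

  if (k != n)
    stop("linear base-suffix derivation emitted ", k, " suffixes for n = ", n)
  if (anyDuplicated(vals) != 0L)
    stop("duplicate base suffix emitted at value ", vals[anyDuplicated(vals)])

  bs <- vector("list", tree$n_nodes)
  grp <- split(vals, nodes)
  touched <- as.integer(names(grp))
  for (j in seq_along(touched)) bs[[touched[j]]] <- sort(grp[[j]])
  for (v in tree$internal_ids) if (is.null(bs[[v]])) bs[[v]] <- integer(0)

  .new_bs_table(tree, bs, "linear",
                list(chain_steps = annotation$chain_steps,
                     record_scan = 2L * n, emissions = n))
}
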