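# Base paths: pairs (top, bottom) of internal nodes, bottom below top, whose
# suffix-link preimage pair never occurs in ancestor/descendant relation.
# Equivalently (Definition-8 form, the oracle): bottom d is base under v
# when d is in PU(v) but not of the form SL(y) for y an internal descendant
# of an OSHR child of v.

.new_bp_table <- function(tree, bp, algorithm, ops) {
  counts <- integer(tree$n_nodes)
  counts[tree$internal_ids] <- lengths(bp[tree$internal_ids])
  structure(
    list(bp = bp, counts = counts, total = sum(counts), n = tree$n,
         n_nodes = tree$n_nodes, sigma = tree$text$sigma,
         algorithm = algorithm, ops = ops),
    class = "base_path_table")
}

#' @export
print.base_path_table <- function(x, ...) {
  cat(sprintf("<base_path_table> [%s] %d base paths (n = %d, sigma = %d; bound sigma*n = %d)\n",
              x$algorithm, x$total, x$n, x$sigma, x$sigma * x$n))
  invisible(x)
}

#' Base paths by explicit set difference (ground truth)
#'
#' For each internal `v`: bottoms are
#' `PU(v) - {SL(y) : y in PU(c), c in SLS(v)}`.  Serves as the oracle for
#' [bp_algorithm4()] and [bp_linear()].
#'
#' @inheritParams bs_oracle
#' @return A `base_path_table`: per internal node the sorted bottom base
#'   node ids, plus the global count and operation counters.
#' @export
bp_oracle <- function(tree, view) {
  .check_view(tree, view)
  bp <- vector("list", tree$n_nodes)
  sl <- tree$suffix_link
  ops <- 0
  for (v in tree$internal_ids) {
    pu <- pu_set(tree, v)
    kids <- sls(view, v)
    ops <- ops + length(pu)
    if (length(kids) == 0L || length(pu) == 0L) {
      bp[[v]] <- pu
      next
    }
    covered <- unlist(lapply(kids, function(c) sl[pu_set(tree, c)]), use.names = FALSE)
    ops <- ops + length(covered)
    bp[[v]] <- sort(setdiff(pu, covered))
  }
  .new_bp_table(tree, bp, "oracle", list(set_elements = ops))
}

#' Base paths via SLS interval containment
#'
#' `(v, d)` is base unless some member of `SLS(d)` is a descendant of some
#' member of `SLS(v)`.  The test binary-searches the sorted DFS intervals
#' of `SLS(v)` for each member of `SLS(d)`: O(nh sigma log2 sigma) overall.
#'
#' @inheritParams bs_oracle
#' @return A `base_path_table` identical to [bp_oracle()]'s.
#' @export
bp_algorithm4 <- function(tree, view) {
  .check_view(tree, view)
  bp <- vector("list", tree$n_nodes)
  ptr <- view$sls_ptr
  ops <- 0
  for (v in tree$internal_ids) {
    pu <- pu_set(tree, v)
    if (length(pu) == 0L) { bp[[v]] <- integer(0); next }
    vkids <- sort(sls(view, v))
    ops <- ops + length(pu)
    if (length(vkids) == 0L) { bp[[v]] <- pu; next }
    lens <- ptr[pu + 1L] - ptr[pu]
    has <- lens > 0L
    if (!any(has)) { bp[[v]] <- pu; next }
    idx <- sequence(lens[has], from = ptr[pu[has]] + 1L)
    ys <- view$sls_ids[idx]
    owner <- rep(which(has), lens[has])
    j <- findInterval(ys, vkids)
    covered_pair <- j >= 1L & ys <= tree$dfs_out[vkids[pmax(j, 1L)]]
    ops <- ops + length(ys) * (1 + ceiling(log2(length(vkids) + 1)))
    covered <- unique(owner[covered_pair])
    bp[[v]] <- if (length(covered) == 0L) pu else pu[-covered]
  }
  .new_bp_table(tree, bp, "algorithm4", list(interval_tests = ops))
}

#' Base paths by merged suffix-link chain walks
#'
#' Enumerates per *bottom* node `d`.  The covered top depths for `d` are
#' the union over `a` in `SLS(d)` of the string depths (minus one) of the
#' proper internal ancestors of `a`.  Candidate tops -- the ancestors of
#' `d` -- are visited deepest-first while one pointer per member of
#' `SLS(d)` climbs its own parent chain monotonically; pointers that meet
#' are merged so shared chain segments are walked once (first-convergence
#' cutoff).  A bottom with empty `SLS(d)` keeps every ancestor (the OSHR
#' leaf case).  Operation counts grow near-linearly in `n` on random
#' strings; worst-case degenerate inputs degrade gracefully.
#'
#' @inheritParams bs_oracle
#' @param annotation accepted for interface symmetry with [bs_linear()]
#'   (the reference-record scan shares the walk machinery); may be `NULL`.
#' @return A `base_path_table` identical to [bp_oracle()]'s.
#' @export
bp_linear <- function(tree, view, annotation = NULL) {
  .check_view(tree, view)
  par <- tree$parent
  dep <- tree$depth
  cap <- tree$text$sigma * tree$n
  tops <- integer(min(cap, 4L * tree$n))
  bots <- integer(length(tops))
  k <- 0L
  ops <- 0L

  bottoms <- tree$internal_ids[tree$internal_ids != 1L]
  for (d in bottoms) {
    ptrs <- par[sls(view, d)]          # proper-ancestor chains of SLS members
    u <- par[d]
    while (!is.na(u)) {
      delta <- dep[u] + 1L
      np <- length(ptrs)
      if (np > 0L) {
        for (i in seq_len(np)) {
          while (dep[ptrs[i]] > delta) {
            ptrs[i] <- par[ptrs[i]]
            ops <- ops + 1L
          }
        }
        if (np > 1L) ptrs <- unique(ptrs)
        ops <- ops + np
        covered <- any(dep[ptrs] == delta)
      } else covered <- FALSE
      if (!covered) {
        k <- k + 1L
        if (k > length(tops)) {        # amortized doubling up to sigma*n
          tops <- c(tops, integer(length(tops)))
          bots <- c(bots, integer(length(bots)))
        }
        tops[k] <- u
        bots[k] <- d
      }
      u <- par[u]
      ops <- ops + 1L
    }
  }

  bp <- vector("list", tree$n_nodes)
  if (k > 0L) {
    grp <- split(bots[seq_len(k)], tops[seq_len(k)])
    touched <- as.integer(names(grp))
    for (j in seq_along(touched)) bp[[touched[j]]] <- sort(grp[[j]])
  }
  for (v in tree$internal_ids) if (is.null(bp[[v]])) bp[[v]] <- integer(0)
  .new_bp_table(tree, bp, "linear", list(walk_steps = ops, emissions = k))
}
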