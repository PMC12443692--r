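# Verification harness, operation-count scaling study, and the CLI.
#
# Operation counts -- not wall clock -- are the performance signal
# throughout: every algorithm returns named counters whose sum is
# deterministic for a fixed input, so scaling conclusions are
# hardware-independent and reproducible.

#' Total instrumented operation count of an algorithm run
#'
#' @param table a `base_suffix_table` or `base_path_table`.
#' @return Numeric scalar: the sum of the run's named counters.
#' @export
op_count <- function(table) sum(unlist(table$ops))

.fixture_battery <- function(sizes, reps, seed, models = c("uniform", "markov", "repeat_heavy")) {
  fixtures <- list()
  for (m in models) for (s in sizes) for (r in seq_len(reps)) {
    sd <- seed + 1000L * match(m, models) + 10L * s + r
    fixtures[[length(fixtures) + 1L]] <-
      list(label = sprintf("%s_n%d_rep%d", m, s, r), seed = sd,
           text = generate_synthetic(m, s, seed = sd))
  }
  # adversarial shapes: maximal height, period two, Fibonacci string
  k <- max(sizes)
  fixtures[[length(fixtures) + 1L]] <-
    list(label = "run_Ak", seed = seed,
         text = generate_synthetic("run", k, alphabet = "A", seed = seed))
  ab <- strrep("AB", ceiling(k / 2))
  fixtures[[length(fixtures) + 1L]] <-
    list(label = "alt_ABk", seed = seed,
         text = st_text(substr(ab, 1L, k), append_sentinel = TRUE))
  fib <- c("A", "AB")
  while (nchar(fib[length(fib)]) < k)
    fib <- c(fib, paste0(fib[length(fib)], fib[length(fib) - 1L]))
  fixtures[[length(fixtures) + 1L]] <-
    list(label = "fibonacci", seed = seed,
         text = st_text(substr(fib[length(fib)], 1L, k), append_sentinel = TRUE))
  fixtures
}

#' Cross-check every base-suffix and base-path algorithm
#'
#' Generates a deterministic battery of synthetic fixtures (three models
#' over the given sizes, plus the single-character run, the period-two
#' string and a Fibonacci string) and asserts on each:
#' all four base-suffix algorithms agree, all three base-path algorithms
#' agree, the base suffixes over all internal nodes are exactly
#' `{0..n-1}` (conservation), and the base-path total is at most
#' `sigma * n`.
#'
#' @param sizes fixture lengths (before the sentinel).
#' @param reps replicates per (model, size).
#' @param seed base seed; each fixture derives its own from it.
#' @return Invisibly, a summary data frame (one row per fixture).  Any
#'   mismatch raises an error naming the fixture seed, the first differing
#'   node and the two sets.
#' @export
run_equivalence_suite <- function(sizes = c(20L, 60L, 150L, 300L), reps = 2L, seed = 1L) {
  fixtures <- .fixture_battery(sizes, reps, seed)
  rows <- vector("list", length(fixtures))
  for (i in seq_along(fixtures)) {
    fx <- fixtures[[i]]
    tr <- build_suffix_tree(fx$text)
    vw <- build_oshr(tr)
    an <- find_reference_annotation(tr, vw)
    bs <- list(oracle = bs_oracle(tr, vw), a1 = bs_algorithm1(tr, vw),
               a2 = bs_algorithm2(tr, vw), a3 = bs_linear(tr, vw, an))
    bp <- list(oracle = bp_oracle(tr, vw), a4 = bp_algorithm4(tr, vw),
               a5 = bp_linear(tr, vw, an))
    for (nm in names(bs)[-1L]) {
      ok <- tables_agree(bs$oracle, bs[[nm]])
      if (!isTRUE(ok)) {
        node <- attr(ok, "first_mismatch")
        stop(sprintf(
          "base-suffix mismatch on fixture '%s' (seed %d), algorithm %s, node %d: oracle {%s} vs {%s}",
          fx$label, fx$seed, nm, node,
          paste(bs$oracle$bs[[node]], collapse = ","),
          paste(bs[[nm]]$bs[[node]], collapse = ",")))
      }
    }
    for (nm in names(bp)[-1L]) {
      ok <- tables_agree(bp$oracle, bp[[nm]])
      if (!isTRUE(ok)) {
        node <- attr(ok, "first_mismatch")
        stop(sprintf(
          "base-path mismatch on fixture '%s' (seed %d), algorithm %s, node %d: oracle {%s} vs {%s}",
          fx$label, fx$seed, nm, node,
          paste(bp$oracle$bp[[node]], collapse = ","),
          paste(bp[[nm]]$bp[[node]], collapse = ",")))
      }
    }
    all_bs <- unlist(bs$oracle$bs[tr$internal_ids], use.names = FALSE)
    if (bs$oracle$total != tr$n || !setequal(all_bs, 0:(tr$n - 1L)))
      stop(sprintf("conservation violated on fixture '%s' (seed %d): %d base suffixes for n = %d",
                   fx$label, fx$seed, bs$oracle$total, tr$n))
    if (bp$oracle$total > tr$text$sigma * tr$n)
      stop(sprintf("base-path bound violated on fixture '%s' (seed %d): %d > sigma*n = %d",
                   fx$label, fx$seed, bp$oracle$total, tr$text$sigma * tr$n))
    rows[[i]] <- data.frame(
      fixture = fx$label, seed = fx$seed, n = tr$n, sigma = tr$text$sigma,
      internal_nodes = tr$n_internal, base_suffixes = bs$oracle$total,
      base_paths = bp$oracle$total, sigma_n_bound = tr$text$sigma * tr$n)
  }
  invisible(do.call(rbind, rows))
}

.algo_registry <- list(
  bs_oracle = function(tr, vw, an) bs_oracle(tr, vw),
  bs_algorithm1 = function(tr, vw, an) bs_algorithm1(tr, vw),
  bs_algorithm2 = function(tr, vw, an) bs_algorithm2(tr, vw),
  bs_linear = function(tr, vw, an) bs_linear(tr, vw, an),
  bp_oracle = function(tr, vw, an) bp_oracle(tr, vw),
  bp_algorithm4 = function(tr, vw, an) bp_algorithm4(tr, vw),
  bp_linear = function(tr, vw, an) bp_linear(tr, vw, an))

#' Operation-count scaling study
#'
#' Runs the chosen algorithms on synthetic texts of increasing size and
#' fits `log(op_count) ~ log(n)` by least squares.  Linear-time algorithms
#' are expected to sit near slope 1 (they are flagged above 1.15); the
#' O(nh) algorithms reach slope 2 on the single-character run, where h is
#' proportional to n.
#'
#' @param algorithms character vector naming algorithms (see
#'   `names(otindex:::.algo_registry)`).
#' @param sizes at least four text lengths spanning at least ~1.5 orders of
#'   magnitude (enforced as `log10(max/min) >= 1.4`).
#' @param model synthetic model passed to [generate_synthetic()].
#' @param seed base seed; each size derives its own.
#' @param alphabet alphabet for the generator.
#' @return A `scaling_report`: list with `points` (algorithm, n, op_count)
#'   and `fits` (algorithm, slope, r_squared, flagged).
#' @export
run_scaling_study <- function(algorithms, sizes, model = "uniform", seed = 1L,
                              alphabet = c("A", "C", "G", "T")) {
  algorithms <- match.arg(algorithms, names(.algo_registry), several.ok = TRUE)
  sizes <- sort(as.integer(sizes))
  if (length(sizes) < 4L)
    stop("at least 4 sizes are required for a scaling fit")
  if (log10(max(sizes) / min(sizes)) < 1.4)
    stop("sizes must span at least ~1.5 orders of magnitude")
  pts <- list()
  for (i in seq_along(sizes)) {
    txt <- generate_synthetic(model, sizes[i], alphabet = alphabet, seed = seed + i)
    tr <- build_suffix_tree(txt)
    vw <- build_oshr(tr)
    an <- if (any(grepl("linear", algorithms))) find_reference_annotation(tr, vw) else NULL
    for (alg in algorithms) {
      tab <- .algo_registry[[alg]](tr, vw, an)
      pts[[length(pts) + 1L]] <- data.frame(
        algorithm = alg, n = tr$n, op_count = op_count(tab))
    }
  }
  points <- do.call(rbind, pts)
  fits <- do.call(rbind, lapply(split(points, points$algorithm), function(df) {
    fit <- stats::lm(log(op_count) ~ log(n), data = df)
    data.frame(algorithm = df$algorithm[1L],
               slope = unname(stats::coef(fit)[2L]),
               r_squared = summary(fit)$r.squared)
  }))
  fits$flagged <- grepl("linear", fits$algorithm) & fits$slope > 1.15
  rownames(fits) <- NULL
  structure(list(points = points, fits = fits, model = model, seed = seed),
            class = "scaling_report")
}

#' @export
print.scaling_report <- function(x, ...) {
  cat(sprintf("<scaling_report> model = %s, seed = %d\n", x$model, x$seed))
  print(x$fits, row.names = FALSE)
  invisible(x)
}
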