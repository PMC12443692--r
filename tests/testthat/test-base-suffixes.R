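# base suffixes: four algorithms against printed values and brute force

bs_all <- function(tr, vw, an = find_reference_annotation(tr, vw)) {
  list(oracle = bs_oracle(tr, vw), a1 = bs_algorithm1(tr, vw),
       a2 = bs_algorithm2(tr, vw), a3 = bs_linear(tr, vw, an))
}

test_that("worked-example base suffixes match the printed sets", {
  tr <- fig1_tree()
  vw <- build_oshr(tr)
  tabs <- bs_all(tr, vw)
  for (tab in tabs) {
    expect_equal(tab$bs[[node_id(tr, "A")]], c(1L, 4L, 6L, 11L, 15L))
    expect_equal(tab$bs[[node_id(tr, "AA")]], integer(0))
    expect_equal(tab$bs[[node_id(tr, "TAA")]], c(7L, 12L, 16L))
    expect_equal(tab$bs[[node_id(tr, "T")]], 14L)
    expect_equal(tab$bs[[node_id(tr, "AT")]], c(5L, 8L))
    expect_equal(tab$total, tr$n)
  }
})

test_that("reference annotation matches the printed examples", {
  tr <- fig1_tree()
  vw <- build_oshr(tr)
  an <- find_reference_annotation(tr, vw)

  # leaf 6 is a reference leaf whose single inbetween node is "TT"
  i <- which(an$leaf_records$suffix == 6L)
  expect_length(i, 1L)
  expect_equal(vapply(an$leaf_chains[[i]], function(v) node_label(tr, v), ""), "TT")

  # node TAA is a reference internal whose single inbetween node is "A"
  j <- which(an$internal_records$A == node_id(tr, "TAA"))
  expect_length(j, 1L)
  expect_equal(an$internal_records$C[j], node_id(tr, "AA"))
  expect_equal(vapply(an$internal_chains[[j]], function(v) node_label(tr, v), ""), "A")

  # the run string: brute force over the definitions gives exactly one
  # reference leaf (suffix 0: SL(parent) = AA but parent(leaf 1) = AAA,
  # whose chain {AAA} carries base suffix 4) and no reference internals
  tr4 <- build_suffix_tree(st_text("AAAA$"))
  an4 <- find_reference_annotation(tr4, build_oshr(tr4))
  expect_equal(an4$leaf_records$suffix, 0L)
  expect_equal(vapply(an4$leaf_chains[[1L]], function(v) node_label(tr4, v), ""), "AAA")
  expect_equal(nrow(an4$internal_records), 0L)
})

test_that("linear-algorithm contributions land where the oracle says", {
  tr <- fig1_tree()
  vw <- build_oshr(tr)
  tab <- bs_oracle(tr, vw)
  # reference leaf 6 contributes depth(TT) + 7 = 9 to BS(TT)
  expect_true(9L %in% tab$bs[[node_id(tr, "TT")]])
  expect_equal(tab$bs[[node_id(tr, "TT")]], c(9L, 10L))
  # reference internal TAA contributes depth(A) + {9,13,4} + 1 to BS(A)
  expect_true(all(c(6L, 11L, 15L) %in% tab$bs[[node_id(tr, "A")]]))
  # suffix 0 is base at every internal ancestor of its leaf
  expect_equal(tab$bs[[1L]], 0L)
  expect_true(1L %in% tab$bs[[node_id(tr, "A")]])
  expect_equal(tab$bs[[node_id(tr, "AG")]], c(2L, 17L))
})

test_that("all four algorithms agree with brute force on small strings", {
  for (seed in c(2L, 9L, 27L)) {
    for (alpha in list(c("A", "C", "G", "T"), c("A", "B"))) {
      txt <- generate_synthetic("uniform", 3L + (seed * 17L) %% 50L,
                                alphabet = alpha, seed = seed)
      tr <- build_suffix_tree(txt)
      vw <- build_oshr(tr)
      for (tab in bs_all(tr, vw))
        expect_table_matches_brute(tr, tab, txt$string, "bs")
    }
  }
})

test_that("algorithms agree pairwise on random and adversarial strings", {
  fixtures <- list(st_text("AAAAAAAAAA$"), st_text("ABABABABAB$"),
                   st_text("ABAABABAABAAB$"))   # run, period-2, Fibonacci
  for (seed in 1:40) {
    alpha <- if (seed %% 3L == 0L) c("A", "B") else c("A", "C", "G", "T")
    model <- c("uniform", "markov", "repeat_heavy")[1L + seed %% 3L]
    fixtures[[length(fixtures) + 1L]] <-
      generate_synthetic(model, 2L + (seed * 43L) %% 299L, alphabet = alpha, seed = seed)
  }
  for (txt in fixtures) {
    tr <- build_suffix_tree(txt)
    vw <- build_oshr(tr)
    tabs <- bs_all(tr, vw)
    for (nm in c("a1", "a2", "a3"))
      expect_true(isTRUE(tables_agree(tabs$oracle, tabs[[nm]])),
                  label = sprintf("%s on '%s...'", nm, substr(txt$string, 1, 20)))
    # Conservation: the union over internal nodes is exactly {0..n-1}
    all_bs <- unlist(tabs$oracle$bs[tr$internal_ids], use.names = FALSE)
    expect_equal(sort(all_bs), 0:(tr$n - 1L))
  }
})

test_that("every base suffix recurs in SU of every OSHR ancestor", {
  for (seed in c(5L, 23L)) {
    txt <- random_text(10L + (seed * 31L) %% 120L, seed = seed)
    tr <- build_suffix_tree(txt)
    vw <- build_oshr(tr)
    tab <- bs_oracle(tr, vw)
    for (v in tr$internal_ids) {
      anc <- oshr_ancestors(vw, v)
      expect_lte(length(anc), tr$height)
      for (a in anc)
        expect_true(all(tab$bs[[v]] %in% su_set(tr, a)))
    }
  }
})

test_that("coverage characterization: gaps in the predecessor's ancestor depths", {
  # s = depth(u) + z is base at ancestor u of leaf z  iff  z = 0 or leaf z-1
  # has no internal ancestor of string depth depth(u) + 1
  for (seed in c(4L, 13L)) {
    txt <- random_text(8L + (seed * 19L) %% 80L, seed = seed + 500L)
    tr <- build_suffix_tree(txt)
    vw <- build_oshr(tr)
    tab <- bs_oracle(tr, vw)
    anc_depths <- function(node) {
      out <- integer(0)
      u <- tr$parent[node]
      while (!is.na(u)) { out <- c(out, tr$depth[u]); u <- tr$parent[u] }
      out
    }
    for (z in 0:(tr$n - 1L)) {
      leaf <- tr$leaf_id_by_suffix[z + 1L]
      pred_depths <- if (z == 0L) integer(0) else anc_depths(tr$leaf_id_by_suffix[z])
      u <- tr$parent[leaf]
      while (!is.na(u)) {
        is_base <- (tr$depth[u] + z) %in% tab$bs[[u]]
        expect_equal(is_base, z == 0L || !((tr$depth[u] + 1L) %in% pred_depths))
        u <- tr$parent[u]
      }
    }
  }
})

test_that("operation counters are deterministic and sized sensibly", {
  txt <- random_text(400L, seed = 77L)
  tr <- build_suffix_tree(txt)
  vw <- build_oshr(tr)
  an <- find_reference_annotation(tr, vw)
  t1 <- bs_algorithm1(tr, vw); t1b <- bs_algorithm1(tr, vw)
  expect_identical(t1$ops, t1b$ops)
  # algorithm 1 touches sum |SU(v)| elements
  expect_equal(op_count(t1), sum(tr$leaf_count[tr$internal_ids]))
  # the linear algorithm emits exactly n suffixes
  t3 <- bs_linear(tr, vw, an)
  expect_equal(t3$ops$emissions, tr$n)
})
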