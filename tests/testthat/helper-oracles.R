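# Brute-force oracles working purely on string labels, independent of the
# suffix-tree implementation.  All positions 0-based; all strings include
# the sentinel.

FIG1 <- "AGCATAATTTAACTAAG$"

# all occurrence start positions of w in s (overlapping)
brute_occ <- function(s, w) {
  n <- nchar(s); m <- nchar(w)
  if (m == 0L) return(0:(n - 1L))
  starts <- integer(0)
  for (i in seq_len(n - m + 1L))
    if (substr(s, i, i + m - 1L) == w) starts <- c(starts, i - 1L)
  starts
}

# internal-node path labels = right-maximal substrings (>= 2 distinct
# following characters), plus the root label ""
brute_internal_labels <- function(s) {
  n <- nchar(s)
  subs <- unique(unlist(lapply(seq_len(n), function(i)
    vapply(i:n, function(j) substr(s, i, j), ""))))
  keep <- vapply(subs, function(w) {
    starts <- brute_occ(s, w)
    nxt <- substr(rep(s, length(starts)), starts + nchar(w) + 1L,
                  starts + nchar(w) + 1L)
    length(unique(nxt[nzchar(nxt)])) >= 2L
  }, TRUE)
  c("", subs[keep])
}

brute_su <- function(s, w) sort(brute_occ(s, w) + nchar(w))

brute_sls <- function(s, labels, w) {
  cand <- paste0(setdiff(unique(strsplit(s, "")[[1]]), ""), w)
  sort(cand[cand %in% labels])
}

brute_bs <- function(s, labels, w) {
  covered <- unlist(lapply(brute_sls(s, labels, w), function(c) brute_su(s, c)))
  sort(setdiff(brute_su(s, w), covered))
}

brute_pu <- function(labels, w) {
  sort(labels[startsWith(labels, w) & labels != w])
}

brute_bp <- function(s, labels, w) {
  covered <- unlist(lapply(brute_sls(s, labels, w), function(c) {
    pu <- brute_pu(labels, c)
    substring(pu, 2L)
  }))
  sort(setdiff(brute_pu(labels, w), covered))
}

# naive O(nm) pattern scan, the oracle for pattern_occurrences()
naive_occurrences <- function(s, pattern) brute_occ(s, pattern)

random_text <- function(n, alphabet = c("A", "C", "G", "T"), seed = 1L) {
  generate_synthetic("uniform", n, alphabet = alphabet, seed = seed)
}

# id of the internal node with the given path label, failing the test if absent
fig1_tree <- function() build_suffix_tree(st_text(FIG1))

node_id <- function(tree, label) {
  id <- node_by_label(tree, label)
  if (is.na(id)) stop("no node with label '", label, "'")
  id
}

# compare an algorithm's per-node table against the label-based oracle
expect_table_matches_brute <- function(tree, tab, s, kind = c("bs", "bp")) {
  kind <- match.arg(kind)
  labels <- brute_internal_labels(s)
  for (w in labels) {
    v <- if (w == "") 1L else node_id(tree, w)
    got <- tab[[kind]][[v]]
    want <- if (kind == "bs") brute_bs(s, labels, w)
            else vapply(brute_bp(s, labels, w), function(b) node_id(tree, b), 1L)
    expect_identical(got, as.integer(sort(unname(want))),
                     label = sprintf("%s at label '%s' of '%s'", kind, w, s))
  }
}
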