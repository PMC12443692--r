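# otindex

Linear-time indexing of the strings under **every** internal node of a
suffix tree.

## What problem this solves, and for whom

Sequence-analysis tools routinely need, for each internal node `x` of a
suffix tree, the set of text positions where the strings below `x` begin:

    SU(x) = { Depth(x) + Suffix_Index(l) : l a leaf under x }

(`Depth(x)` = string depth, the total edge-label length from the root).
Materialising these sets naively costs `O(nh)` for a text of length `n` and
tree height `h` — quadratic on repetitive inputs.  This package implements
an `O(Σn)` alternative built on two ideas:

* the **OSHR tree**: reverse all suffix links over the internal nodes.
  If `SL(a) = b` then `SU(a) ⊆ SU(b)`, so a post-order traversal of this
  tree lets each node inherit its children's indexing;
* **base suffixes**: the elements of `SU(x)` not present under any OSHR
  child of `x`.  Over all internal nodes these are exactly `{0, …, n−1}`,
  each once.  Appending them in OSHR post-order to one global list — the
  **OT index** — and recording per-node offsets `(Left, Right)` makes every
  `SU(x)` a contiguous slice of a single length-`n` permutation.

The same construction applied to the labels of internal-node-to-
internal-node paths gives **base paths** (at most `Σn` of them).

The package is aimed at people building string-index infrastructure:
it provides the data structures, five enumeration algorithms (two
ground-truth oracles, two `O(nh·…)` algorithms, two linear ones driven by
*reference leaf/internal nodes*), an exact-pattern-matching demo on top of
the OT index, a verification harness that cross-checks every algorithm
against brute force, an operation-count scaling study, and a CLI.

## Worked example

The 18-character string `AGCATAATTTAACTAAG$` (sentinel appended by the
constructor):

```r
library(otindex)
txt  <- st_text("AGCATAATTTAACTAAG", append_sentinel = TRUE)
tree <- build_suffix_tree(txt)
tree
#> <suffix_tree> text n = 18 (sigma = 5), 28 nodes: 18 leaves + 10 internal, height = 3

view <- build_oshr(tree)
view
#> <oshr_view> 10 internal nodes: 5 OSHR leaves, 5 OSHR internal

taa <- node_by_label(tree, "TAA")
s_set(tree, taa)    # leaf suffix indexes under the node labelled TAA
#> [1]  4  9 13
su_set(tree, taa)   # shifted by Depth(TAA) = 3: positions after the TAA prefix
#> [1]  7 12 16

tab <- bs_linear(tree, view, find_reference_annotation(tree, view))
tab
#> <base_suffix_table> [linear] 18 base suffixes over 10 internal nodes (n = 18), ops = 78
tab$bs[[node_by_label(tree, "A")]]   # base suffixes of node "A"
#> [1]  1  4  6 11 15

idx <- build_ot_suffix_index(tree, view, tab)
c(idx$left[1], idx$right[1])         # root slice covers the whole permutation
#> [1]  0 17
pattern_occurrences(tree, idx, "TAA")
#> [1]  4  9 13

bp_linear(tree, view)
#> <base_path_table> [linear] 10 base paths (n = 18, sigma = 5; bound sigma*n = 90)
```

Reading the numbers: `TAA` occurs at positions 4, 9 and 13; the 18 base
suffixes partition `{0..17}` across the 10 internal nodes (conservation);
the base suffixes of node `A` are the five positions of suffixes that
first become indexable at `A`; the 10 base paths are well under the
`Σn = 90` bound.

Restricting the OT index to the OSHR subtree rooted at the node labelled
`T` reproduces the textbook offsets: `ot_list = [5, 8, 9, 10, 14]` with
`AT = (0,1)`, `TT = (2,3)`, `T = (0,4)`:

```r
build_ot_suffix_index(tree, view, tab, subtree_root = node_by_label(tree, "T"))$ot_list
#> [1]  5  8  9 10 14
```

## Command line

```sh
Rscript -e 'quit(status = otindex::ot_cli())' build --input genome.fa
Rscript -e 'quit(status = otindex::ot_cli())' query --input genome.fa --pattern TAA
Rscript -e 'quit(status = otindex::ot_cli())' verify --quick --text AGCATAATTTAACTAAG
Rscript -e 'quit(status = otindex::ot_cli())' synth --model run --length 4 --alphabet A
Rscript -e 'quit(status = otindex::ot_cli())' scale --algos a3,a5 --sizes 10000,30000,100000,300000
```

`build` prints the structural counts (leaves, internal nodes, OSHR
leaf/internal nodes, alphabet size with and without sentinel); `verify`
cross-checks all algorithms and the OT invariants (exit 1 on failure);
`scale` fits log–log operation counts.  Exit codes: 0 ok, 1 verification
failure, 2 usage error.

## Documentation

The methods vignette (`vignettes/ot-indexing.Rmd`) explains the model, the
gap characterisation behind the linear algorithms, the design choices and
their rationale, what the synthetic fixtures do and do not emulate, and
known limitations.
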