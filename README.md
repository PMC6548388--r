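# bnsplit

Blank-node-safe splitting of RDF N-Triples files for parallel loading into
triple stores.

## The problem

Loading a very large RDF graph into a triple store goes much faster when
the input is split into several files and loaded in parallel — stores such
as Virtuoso and Stardog support this directly. But blank nodes make naive
line-wise splitting incorrect: a blank-node label (`_:b1`) has meaning only
within a single file, so if two triples mentioning the same blank node land
in different files, the store materializes two distinct nodes and the
loaded graph is no longer isomorphic to the original. Life-science RDF
releases routinely contain millions of triples whose subject *and* object
are both blank nodes, which chains blank nodes together and makes the
problem non-trivial.

`bnsplit` splits an N-Triples file into *m* files that are safe to load in
parallel: **no blank node ever occurs in two output files**, every input
triple appears in exactly one output (byte-for-byte the original line),
and the largest file is as small as the blank-node structure allows.

## The method

Given triples T and a file count m, the splitter solves

> find m disjoint sets D₁,…,Dₘ covering T, minimizing maxᵢ |Dᵢ|, such
> that no blank node occurs in two different Dᵢ

in two stages:

1. **Grouping.** Triples are classed by blank content (b2 = both subject
   and object blank, b1 = exactly one, plain = none). Blank labels linked
   by b2 triples form an undirected graph whose connected components are
   computed with union-find; b1 triples join the component of their label;
   plain triples are singletons. The resulting groups are the *finest*
   partition that never separates a blank node (provably: blank sets of
   distinct groups are disjoint, and every bipartition of a group shares a
   blank label across the cut).
2. **Packing.** Groups are packed into m bins with the
   longest-processing-time (LPT) scheduling heuristic — sort groups by
   decreasing size, always fill the least-loaded bin — whose makespan is
   within 4/3 − 1/(3m) of the NP-hard optimum. Plain triples are added in
   bulk by an analytic water-fill that is exactly equivalent to LPT over
   the singletons.

Grouping is a two-pass stream: pass 1 keeps only blank-label vectors and
counters, pass 2 routes each raw input line to its part file. Memory
scales with the number of blank-containing triples, not file size, and no
triple is ever re-serialized.

Verification tools reproduce, without a triple store, the checks a loader
would allow: per-blank-node triple-count profiles (the result of SPARQL
`COUNT(*)` with `isBlank` filters, label-free and thus loader-invariant),
multiset conservation, and — on small instances — an exact blank-node
bijection (RDF isomorphism) search.

## Worked example

```r
library(bnsplit)
d <- tempfile("demo"); dir.create(d)
f <- file.path(d, "bench.nt")

spec <- synthetic_graph_spec("watts_strogatz", n = 200, d = 2, p = 0.5,
                             blank_ratio = 0.5, seed = 5)
make_dataset(spec, f)
#> <dataset_summary: /tmp/.../bench.nt>
#>   200 triples over 184 nodes (92 blank); classes: b2 = 46, b1 = 109, plain = 45

man <- run_split(f, m = 4, output_dir = d)
man
#> <split_manifest: /tmp/.../bench.nt -> 4 parts>
#>   200 triples (0 skipped lines), 91 groups (46 with blanks over 92 labels)
#>   makespan 50; part sizes: 50 50 50 50
#>   timing [s]: group 0.01, combine 0.00, route 0.01 (total 0.02)

run_verify(f, man$outputs)
#> <verify_report: PASS>
#> <conservation_report: PASS>
#>   [ok] triple count
#>   [ok] blank-free lines (multiset)
#>   [ok] blank-containing triples (label-masked multiset)
#>   [ok] blank-node profiles
```

Reading the output: the 200-triple benchmark graph (half its nodes blank)
decomposes into 91 groups — 46 of them holding the 92 blank labels, 45
plain singletons — and LPT packs them into four files of exactly 50
triples each (makespan 50, a perfect balance here). Verification confirms
that every line is conserved and that the per-blank-node triple counts of
the four parts, taken as independently loaded files, match the original.

The same pipeline is available from a shell via the script in `inst/cli/`:

```sh
bnsplit generate --model watts-strogatz --n 200 --d 2 --p 0.5 \
        --blank-ratio 0.5 --seed 5 -o bench.nt
bnsplit split bench.nt 4
bnsplit verify bench.nt bench.part*.nt
```

For files whose blank structure is dominated by one giant connected
component (e.g. dense preferential-attachment graphs at blank ratio 0.5),
the file holding that component cannot be smaller than the component
itself; the manifest's `largest_group` tells you when the makespan is
pinned by that lower bound rather than by packing quality.

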