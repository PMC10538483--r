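# decyclemin

Low-density minimizer sketching for DNA sequences using k-mer orders built
on Mykkeltveit minimum decycling sets (MDS), with an O(k) on-the-fly
membership test so the orders scale to any k — no exponential-size set is
ever constructed or stored.

## The problem

Minimizer schemes sketch a sequence by selecting, from every window of
`w` overlapping k-mers (an `L = w + k − 1` nt window), the k-mer that is
minimal under a total order `o`, leftmost on ties. Every window contributes
a selected k-mer (the *window guarantee*), which is what assemblers,
read mappers and k-mer indexes rely on. The cost of a scheme is its
*density* — the fraction of k-mer positions selected — usually reported as
the *density factor*, density × (w + 1). A random order has expected factor
2; orders whose first priority class is a universal hitting set do better,
but those sets can only be built for k ≤ 13.

This package closes that gap with *partition-compatible* orders whose first
class is the Mykkeltveit minimum decycling set `D_k` of the order-k de
Bruijn graph: one k-mer per pure (rotation) cycle, chosen by the complex
embedding

    M(x) = ( Σᵢ xᵢ cos(2πi/k) ,  Σᵢ xᵢ sin(2πi/k) ),   A=0, C=1, G=2, T=3.

A k-mer is in `D_k` iff it is the first counterclockwise rotation of its
cycle with positive imaginary part `I(x)` — testable in O(k) by comparing
`I(x)` with `I(x′)` of its clockwise rotation — or, for cycles embedding at
the origin, the lexicographically smallest rotation. The *double decycling*
order adds the mirrored (first-negative) set `D̃_k` as a second class, which
lowers density further when `L ≲ 2k`. Baselines included: random and
lexicographic orders, orders from user-supplied k-mer set files
(DOCKS/PASHA-style, one k-mer per line), and Miniception.

## Worked example

```r
library(decyclemin)

in_decycling_set("ACTAC")   # TRUE  — first positive rotation of its cycle
in_decycling_set("ACACT")   # FALSE — same cycle, different rotation
mykkeltveit_embed("ACTAC")[["I"]]   # 1.763356 (> 0)
length(enumerate_decycling_set(5))  # 208 = one k-mer per pure cycle

o <- minimizer_order("double_decycling", k = 5, seed = 3)
select_minimizers("CGGTGCGCCTTGTTCGTGCTGTTCGGCT", o, L = 20)
#> $positions
#> [1] 8          # 0-based k-mer start; CTTGT is in D_5 and wins every window
#> $n_windows
#> [1] 9

expected_density("random",           11, L = 100)$mean_density_factor  # 1.985
expected_density("decycling",        11, L = 100)$mean_density_factor  # 1.909
expected_density("double_decycling", 11, L = 100)$mean_density_factor  # 1.909
```

The three density calls (5 replicates × 1 Mnt i.i.d. sequence, paired
seeds) reproduce the headline ordering: decycling-based orders select
fewer positions than a random order at the same (k, L), and the double
variant is at least as good — its advantage grows with k and shrinks as L
grows past ~2.5k.

A command-line tool wraps the same functions
(`member`, `build-set`, `minimize`, `density`, `sweep`, `gen`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli/decyclemin.R", package="decyclemin"))')
Rscript $CLI member ACTAC
# ACTAC  k=5  I=1.763355757  member=true     (exit code 0 iff member)
Rscript $CLI minimize -i genome.fa -k 31 -L 100 --order double_decycling \
        --seed 1 -o mins.tsv
Rscript $CLI density --expected -k 11 -L 100 --order decycling -o out.csv
```

`minimize` writes 0-based positions with the k-mer and its partition rank;
`density` reports density, density factor and the forward-scheme lower
bound; all outputs carry their full run configuration in `#` headers and
rerun byte-identically for the same configuration.

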