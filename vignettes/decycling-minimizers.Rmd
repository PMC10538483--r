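---
title: "Decycling-set-based minimizer orders: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decycling-set-based minimizer orders: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decyclemin)
```

## The sketching model

A minimizer scheme with parameters $(k, w)$ slides a window of $w$
overlapping k-mers (an $L = w + k - 1$ nt window) along a DNA sequence and
selects from each window the k-mer that is minimal under a total order $o$,
breaking ties by the leftmost position. Every $L$-long window therefore
contributes at least one selected position (the *window guarantee*), and the
selected positions never move backwards as the window slides (minimizers are
a *forward* scheme). The *density* of a scheme on a sequence is the fraction
of k-mer start positions selected; the *density factor* is density times
$(w + 1)$, which makes schemes comparable across window sizes. A random
order has expected density factor 2; the point of this package is orders
that do better, uniformly in $k$.

All orders here are *partition-compatible*: an ordered partition
$\Pi = [C_1, \dots, C_m]$ of the $4^k$ k-mers decides between classes
(members of $C_1$ come first), and a pseudorandom hash decides within a
class. The hash is an XOR of the 2k-bit encoding (A=0, C=1, G=2, T=3, two
bits per base) with a fixed mask, which is a bijection, so the order is
strict on distinct k-mers.

## The decycling partition and the O(k) membership test

The complete de Bruijn graph of order $k$ is partitioned by *pure cycles*:
the cyclic rotation classes of k-mers. Mykkeltveit's minimum decycling set
$D_k$ picks one node per pure cycle, chosen via the embedding
$$M(x) = \Bigl(\sum_{i=0}^{k-1} x_i \cos(2\pi i/k),\;
               \sum_{i=0}^{k-1} x_i \sin(2\pi i/k)\Bigr),$$
with $x_i$ the numeric encoding of character $i$: the class representative
is the first counterclockwise rotation whose imaginary part $I(x)$ is
positive, i.e. the rotation with $I(x) > 0$ whose one-letter clockwise
rotation $x'$ has $I(x') \le 0$. Classes whose rotations all embed at the
origin contribute their lexicographically smallest rotation. Removing $D_k$
leaves an acyclic graph, and on any remaining path every positive node
precedes every nonpositive node; the mirrored set $\tilde{D}_k$ (first
*negative* rotation) gives the complementary statement, which motivates the
three-class *double decycling* partition
$\{D_k,\ \tilde{D}_k \setminus D_k,\ \text{rest}\}$: windows rarely survive
both removals, so low-rank k-mers are found in almost every window.

Membership is decided in $O(k)$ per k-mer: one pass accumulates both $I(x)$
and $I(x')$ (the clockwise rotation's imaginary part reuses the same digit
sweep with a shifted table), and the all-zero branch runs a single
2k-comparison scan for the smallest-rotation test. Nothing is precomputed or
stored per k — this is what lets the orders run at $k = 100$ and beyond,
where the set itself ($\Theta(4^k/k)$ k-mers) could never be materialized.

## Numerical choices

* **Zero tolerance.** Exact arithmetic would test $I(x) = 0$; in doubles we
  use $|I(x)| \le \varepsilon$ with $\varepsilon = 10^{-9} k$ (configurable
  via the `epsilon` argument). "Positive" means $I(x) > \varepsilon$ and
  "nonpositive" means $I(x) \le \varepsilon$; the symmetric variant mirrors
  with $-\varepsilon$. The test suite audits the choice by scanning all
  k-mers for $k \le 12$: computed zeros stay below $10^{-12}$ while the
  smallest genuine non-zero $|I|$ stays more than two orders of magnitude
  above $\varepsilon$, so no misclassification is possible at audited
  scales. Whether near-cancellation could narrow that gap for very large
  $k$ is untested beyond $k \approx 12$; we flag this rather than guess.
* **Zero-class representative of the symmetric set.** The mirror set is
  defined only "by symmetry", which leaves the all-zero classes unspecified.
  We reuse the lexicographically-smallest rule, so zero-class
  representatives are shared between $D_k$ and $\tilde{D}_k$; the
  three-block partition absorbs the overlap and both sets remain valid
  minimum decycling sets with exactly one member per pure cycle.
* **Summation order** is fixed (i = 0..k-1) and trigonometric tables are
  computed once per call, so results are bit-reproducible run to run.
* **Ties** inside a window are always resolved positionally (leftmost);
  order comparison returns equality only for identical k-mers, which the
  XOR bijection guarantees.
* **Seeds.** A user seed feeds R's Mersenne-Twister, which draws the 2k-bit
  mask as k uniform base-4 digits (big-endian fill). Seed 0 is reserved for
  the all-zero mask, i.e. plain lexicographic order within classes. The
  mask, not the seed, defines the order.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `k` | k-mer length (nt) | — | any positive k; digit-vector arithmetic, no 64-bit ceiling |
| `w` / `L` | window in k-mers / nt | — | `L = w + k - 1`; either may be given |
| `seed` | XOR-mask seed | 1 | 0 = lexicographic within classes |
| `epsilon` | zero band for $I(x)$ | `1e-9 * k` | audited for k ≤ 12 |
| `k0` | Miniception inner length | `max(k - w, 3)` | the regime the construction was designed for |
| `n_reps`, `seq_len` | evaluation replicates / length | 5, 1e6 | see below |

The Miniception baseline declares a k-mer a set member iff the minimal
k0-mer it contains (under an inner XOR order, leftmost ties) is its first or
last k0-mer; this set is a universal hitting set computable on the fly, and
its order is built the same partition-compatible way.

## What the synthetic generator emulates — and what it does not

`generate_iid_sequence()` draws each base independently and uniformly. This
is the standard substrate for *expected* density: it has no repeats, no
composition bias and no soft-masked or ambiguous bases. Real genomes have
all three; on them *particular* density is typically slightly higher and
more variable because k-mer usage is non-uniform. Passing density tests on
i.i.d. sequences therefore validates the scheme machinery and the ordering
trends, not genome-specific density values; `particular_density()` accepts
any FASTA for the latter, splitting at non-ACGT characters and excluding
runs shorter than $L$ from both numerator and denominator (they admit no
window, so including their positions would measure fragmentation, not the
scheme).

Evaluation defaults are 5 replicates of 1 Mnt (each replicate gets its own
sequence seed and order seed derived from `base_seed`, so different order
kinds are compared paired). These desk-scale defaults estimate mean density
factors to roughly ±0.01–0.05; both knobs are arguments.

## Known limitations

* The density factor of XOR-mask random minimizers is *right-skewed across
  masks*: most masks give factors slightly below 2 (≈1.96–1.98 at k = 11,
  w = 90) while occasional masks — those whose leading digits form
  self-overlapping patterns that clump low-key positions — give factors
  well above 2, with the mean at 2. With only 5 replicates the sample
  standard error can understate this skew, so a "within 3 SE of 2" check is
  occasionally failed by an unlucky (all-bulk) seed set even though the
  estimator is unbiased. More replicates (the generator's `n_reps`) smooth
  this out.
* The decycling order's factor approaches the random level from below as
  $L$ grows but the approach is slow: at $k = 11$ it is still ≈0.02 below 2
  at $L = 400$ and reaches 2 within sampling error only around
  $L \approx 800$. Because the MDS partition suppresses mask-to-mask
  variance (the selected k-mers are mostly set members regardless of the
  mask), its standard errors are small, which makes tight equality checks
  against the asymptote demanding at moderate $L$.
* The forward-scheme lower bound implemented in
  `lower_bound_density_factor()` is
  $(1.5 + \max(0, \lceil (k-w)/w \rceil) + 1/(2w))/(w+k)$ as a density,
  reported as a factor; it converges to 1.5 for fixed $k$ as $w$ grows and
  is not known to be tight for minimizers — the measured gap between the
  MDS orders (→ 2) and the bound (→ 1.5) is expected.
* Explicit enumeration (`enumerate_decycling_set()`) filters all $4^k$
  k-mers through the membership test and is deliberately capped at
  $k \le 12$; the on-the-fly test is the intended interface above that.
  `verify_decycling()` builds the full graph and is capped at $k \le 8$.
* Reverse-complement canonicalization is out of scope: the orders never
  canonicalize, matching the construction they implement.

## Worked check

```{r anchors}
in_decycling_set("ACTAC")     # first positive rotation of its class
in_decycling_set("ACACT")     # same class, different rotation
mykkeltveit_embed("ACTAC")[["I"]]
length(enumerate_decycling_set(5))  # one per pure cycle: 208 necklaces
```

```{r density, eval = FALSE}
# ordering trend at k = 11, L = 100 (5 x 1 Mnt, paired seeds)
expected_density("random",           11, L = 100)$mean_density_factor
expected_density("decycling",        11, L = 100)$mean_density_factor
expected_density("double_decycling", 11, L = 100)$mean_density_factor
```
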