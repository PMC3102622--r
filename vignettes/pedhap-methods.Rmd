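---
title: "Methods: haplotypes versus genotypes on pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotypes versus genotypes on pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedhap)
```

This vignette records the model conventions, the proxy-family reduction
and its transmission chain, and the exact validity domains of the
identities the package relies on. It is the reference for choices that
are not forced by the mathematics and for one place where the package
deliberately departs from a commonly printed form of the transmission
chain.

## 1. The inheritance-vector HMM

A pedigree is a set of individuals $I$ with a father and mother recorded
for each non-founder. Each non-founder contributes two *meioses*
(maternal and paternal); each meiosis carries, at each locus $j$, a
binary origin bit saying which of the parent's two haplotypes was
copied. The vector of all origin bits at locus $j$ is the *inheritance
state* $x_j \in \{0,1\}^{2|I \setminus F|}$, where $F$ is the founder
set.

* **Prior.** $x_1$ is uniform: $P(x_1) = 2^{-2|I \setminus F|}$.
* **Transitions.** Between loci $j$ and $j+1$, each bit flips
  independently with the interval's recombination fraction $\theta_j$:
  $P(x_{j+1} \mid x_j) = \theta_j^{d}(1-\theta_j)^{b-d}$ with $d$ the
  Hamming distance and $b$ the number of bits.
* **Emissions.** Conditional on $x_j$, every allele in the pedigree at
  locus $j$ descends from one of the $2|F|$ founder *slots*. Founder
  alleles are i.i.d. uniform on $\{1, \dots, k_j\}$. The emission
  probability of the observed data at locus $j$ is the probability, over
  this founder-allele prior, that every observation is satisfied.

`forward_backward()` runs a scaled forward–backward pass over this chain.
Transition products use the factorized per-bit structure (a sequence of
bit-flip permutations) rather than dense $S \times S$ matrices, so a
transition step costs $O(S \cdot b)$. `recombination_distribution()`
augments the forward pass with a count dimension: it propagates a matrix
$W[x, r]$ of mass reaching state $x$ with exactly $r$ bit flips in the
chosen interval, then contracts with the backward vector.
`min_recombination()` replaces sum–product with min–sum on the same
state space; `max_probability()` replaces it with max–product.

### Orientation of haplotype observations

A haplotype observation gives two allele sequences per individual but
does not say which is maternal. The package handles this with one extra
*orientation bit* per typed non-founder **whose two sequences differ**:
the bit chooses which observed sequence is the maternal one. Typed
founders need no orientation bit because founder haplotypes are
exchangeable under the i.i.d. founder prior — both orientations
contribute identical mass, and the package fixes the founder's first
observed sequence as haplotype 1 (a *founder-canonical* labeling).
Individuals whose two sequences are identical also need no bit. This
convention changes nothing observable: likelihoods, posteriors and
minimum counts are invariant to it, and the test suite checks the
forward–backward likelihood against a brute-force enumeration that
marginalizes orientations explicitly.

### State-space caps

The full state space has $2^b$ states with $b$ = (2 × non-founders) +
orientation bits. `forward_backward()` and friends take a `max_states`
argument (default $2^{20}$) and refuse, before allocating anything,
instances whose state space exceeds it. The sizes used throughout the
tests and experiments (pedigrees of up to ~12 individuals, proxy
pedigrees with one or two genotyped individuals) are the package
author's choices to keep exhaustive oracles feasible; nothing in the
algorithms is specific to those sizes.

## 2. The proxy-family reduction

`build_proxy_pedigree()` maps a genotype instance to a haplotype
instance. For each genotyped individual $i$ with sorted genotype pairs
$\{g_{j1} \le g_{j2}\}$ it adds a founder spouse `i#0`, homozygous
all-ones, and four children `i#1` … `i#4` of $i$ and `i#0`. Every
child's spouse-derived haplotype is all ones; the haplotypes inherited
from $i$ are:

* `i#1`: the smaller allele $g_{j1}$ at every locus;
* `i#2`: the larger allele $g_{j2}$ at every locus;
* `i#3`: the smaller allele at the 1st, 3rd, … *heterozygous* locus and
  the larger at the 2nd, 4th, …; `i#4` complementary. At homozygous loci
  both carry the single allele.

Only the $5|G|$ new individuals are typed in the mapped instance. The
union of the children's $i$-derived alleles pins $i$'s genotype, and the
alternation of `i#3`/`i#4` forces recombinations between consecutive
heterozygous loci.

**Lemma 1 (minimum recombinations, exact).** Writing $T_i$ for the
number of heterozygous loci of $i$,
$$R_{\min}(\text{mapped}) = R_{\min}(\text{original}) +
  \sum_{i \in G} 2\,\max(T_i - 1, 0),$$
the offset computed by `min_recomb_offset()`. Any extra recombination a
"cheating" configuration saves inside a proxy family costs at least two
elsewhere, so the identity holds for arbitrary genotypes, including
homozygous loci. The test suite verifies it on random instances against
an independent brute-force enumerator.

### The 16-state transmission chain

Condition on $i$'s own (phased) haplotypes. The four children's
$i$-derived origin bits form a 16-state chain with uniform initial
distribution and the per-bit flip transition `transmission_matrices()$P`.
Suppose $i$ is heterozygous at loci $t_1 < \dots < t_T$ and (in one
phasing) carries the smaller allele on haplotype 1 at every heterozygous
locus. Reading the required children's bits (order `i#1 i#2 i#3 i#4`,
`i#1` most significant):

* at $t_1, t_3, \dots$ (odd-indexed heterozygous loci) the state must be
  `0101` — `i#1` and `i#3` copy haplotype 1 (smaller), `i#2` and `i#4`
  haplotype 2 (larger);
* at $t_2, t_4, \dots$ the state must be `0110`.

Consecutive required states are at Hamming distance **2** (bits `i#3`
and `i#4` flip; `i#1` and `i#2` never do). With the complementary
phasing the states are `1010`/`1001` — again distance 2 — and because
the per-gap factor $f^2(1-f)^2$ is symmetric in $f \leftrightarrow 1-f$,
the transmission probability is the same for either phasing:
$$p_t = \frac{1}{16} \prod_{m=1}^{T-1} \delta_m^2 (1-\delta_m)^2,
  \qquad \delta_m = \tfrac{1}{2}\Bigl(1 - \prod_{l=t_m}^{t_{m+1}-1}
  (1 - 2\theta_l)\Bigr),$$
where $\delta_m$ is the net flip probability across the homozygous gap
(`transmission_probability()`). Checkpoints: $p_t = 1$ for $T \le 1$;
$p_t = 1/256$ for $T = 2$ at $\theta = 1/2$; $p_t = 0$ at $\theta = 0$
with $T \ge 2$.

A form of this chain sometimes displayed elsewhere projects onto the
state pair `0110`/`1001`, which are at Hamming distance 4 and give
per-gap factors $\delta^4$. That contradicts the distance-2 structure
derived above and disagrees numerically with exhaustive path enumeration
(by factors up to ~80× on two-locus cases), so the package uses the
distance-2 pair `0101`/`0110`. The correctness of this choice is pinned
in the tests by comparing `proxy_constant()` against a brute-force
oracle that shares no code with the production chain.

**Lemma 2 (conditional likelihood, exact).** For every inheritance
configuration $x$ of the *original* pedigree and any fixed phasing of
$i$'s haplotypes, the mapped instance's probability factorizes as the
original's times $\prod_{i \in G} c_i$ with
$$c_i = p_t^{(i)} \times \prod_{j=1}^{L} k_j^{-2},$$
the `proxy_constant()`. The factor $\prod_j k_j^{-2}$ is the founder
prior of the all-ones spouse's two haplotypes — it must be included
because the spouse is a new founder whose haplotypes are fixed by the
observations.

**Corollary 3 (unconditional likelihood) and its validity domain.** The
unconditional identity
$L(\text{mapped}) = L(\text{original}) \times \prod_i c_i$
holds exactly **when every genotyped individual is heterozygous at every
locus**. With homozygous loci it fails (slightly, upward): at a
homozygous locus the mapped instance also admits configurations in which
$i$ is heterozygous yet all four children happen to draw the same
haplotype, mass that has no counterpart factorization. The smallest
counterexample — a lone genotyped founder, one homozygous locus, one
heterozygous locus — gives $9/128$ versus $8/128$. Accordingly:

* `verify_proportionality()` checks the unconditional identity and is
  exercised in the tests on fully heterozygous genotypes;
* the conditional Lemma-2 identity is tested with homozygous runs and
  both phasings, where it is exact;
* Lemma 1 is unaffected (the leaking configurations pay at least two
  extra recombinations per gap).

### Sizes

The mapped pedigree has $|I| + 5|G|$ individuals and $|E| + 8|G|$
parent–child edges, of which $5|G|$ individuals are haplotyped: 5 newly
haplotyped individuals per genotyped one, and a size inflation of at
most 6× (attained when everyone is genotyped).

## 3. Fully haplotyped pedigrees

When every individual is haplotyped, the problem decomposes over
father–mother–child trios: each child's two haplotypes must be chosen,
per orientation, from its parents' observed sequences, and the
likelihood/min-count factorizes into per-trio, per-meiosis terms.
`trio_likelihood()` and `trio_min_recombinations()` implement the
4-state trio chain; `fully_typed_likelihood()` and
`fully_typed_min_recombination()` combine trios over the pedigree,
marginalizing (resp. minimizing over) each individual's orientation.
The tests confirm equality with the general HMM on random pedigrees.

## 4. Simulator and experiments

`default_scenario()` encodes the study design: 40 biallelic SNPs, all
intervals tight ($\theta = 0.01$) except a central breakpoint interval
($\theta = 0.25$); founder haplotypes drawn i.i.d. per locus from
uniform allele frequencies. The pool is a stand-in for a population
haplotype panel and reproduces linkage only through the map — there is
no founder linkage disequilibrium, a deliberate simplification.
`sim_gene_drop()` drops genes down the pedigree, recording the true
origin-bit paths and per-interval recombination counts; each replicate
is independently reproducible from `(seed, replicate)`.

`run_accuracy_experiment()` compares, replicate by replicate, the
posterior recombination-count distribution in the central interval
computed from haplotype data versus genotype data on the same simulated
alleles, under a schedule of conditions that successively remove
founders from the typed set. The accuracy score of an estimated pmf $x$
against true count $a$ is
$$\mathrm{acc} = 2 - \sum_r |x_r - \mathbf{1}[r = a]|
  = 2\,x_a \in [0, 2],$$
implemented by `recomb_accuracy()`: 2 for a point mass on the truth, 0
for a distribution placing no mass on it. The experiment defaults to 200
replicates per condition; the summary reports the mean, its standard
error and $n$ per condition and data kind. Tie-breaking in
`min_recombination()`/`max_probability()` is deterministic
(lowest state index first), so all results are reproducible.
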