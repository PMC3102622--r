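# pedhap

Likelihoods, minimum-recombination counts and recombination-count
posteriors on pedigrees, for marker data observed either as **genotypes**
(unordered allele pairs per locus) or as **haplotypes** (two allele
sequences per individual, with unknown parental origin). The package
implements the inheritance-vector hidden Markov model on general
pedigrees, fast special-case algorithms for fully haplotyped data, and
the *proxy-family reduction* that maps any genotyped instance into a
haplotyped instance on an enlarged pedigree — so that haplotype-only
algorithms can answer genotype questions, and so that the two data
representations can be compared on equal footing.

## The model in one paragraph

Each non-founder receives one maternal and one paternal haplotype; at
each locus every meiosis carries a binary origin bit (which grandparental
haplotype was copied). The vector of origin bits across all meioses is
the *inheritance state*; it evolves along the chromosome as a Markov
chain in which each bit flips independently with the interval's
recombination fraction `theta`. Founder haplotypes are i.i.d. uniform
over the allele alphabet. Observed genotypes or haplotypes constrain
which inheritance states and founder-allele assignments are possible;
summing gives the likelihood, minimizing bit flips gives the minimum
recombination count, and forward–backward gives posteriors such as the
distribution of the number of recombinations in a chosen interval.

## The reduction in one paragraph

A genotyped individual `i` with genotype `g_i1 … g_iL` is replaced by a
small *proxy family*: `i` gains an all-ones spouse `i#0` and four fully
haplotyped children `i#1 … i#4` whose haplotypes encode `g_i` in such a
way that (a) the minimum recombination count of the mapped instance
equals that of the original plus a computable offset
(`min_recomb_offset()`), and (b) for fully heterozygous genotypes the
mapped likelihood equals the original likelihood times a computable
constant (`proxy_constant()`). The mapped pedigree has `|I| + 5|G|`
individuals and `5|G|` of them are haplotyped — so each genotyped
individual yields 5 haplotyped ones and the pedigree grows by at most a
factor of 6. See `?build_proxy_pedigree` and the vignette for the exact
statements and their validity domains.

## Worked example

```r
library(pedhap)

# A half-sib pedigree: mother m has children c1 (with f1) and c2 (with f2)
ped <- pedigree(c("f1", "m", "f2", "c1", "c2"),
                father = c(NA, NA, NA, "f1", "f2"),
                mother = c(NA, NA, NA, "m", "m"))
ped
#> Pedigree: 5 individuals (3 founders, 2 non-founders)
#>  id father mother
#>  f1   <NA>   <NA>
#>   m   <NA>   <NA>
#>  f2   <NA>   <NA>
#>  c1     f1      m
#>  c2     f2      m

# Four biallelic markers; a loose central interval flanked by tight ones
map <- marker_map(c(2L, 2L, 2L, 2L), theta = c(0.05, 0.3, 0.05))

# Simulate one gene-dropping replicate and type only the children
sc  <- default_scenario(ped, seed = 42, loci = 4,
                        theta_central = 0.3, theta_tight = 0.05)
sim <- sim_gene_drop(sc, replicate = 1)
obs <- mask_data(sim, untyped = c("f1", "f2"))

# Likelihood of the same alleles seen as genotypes vs as haplotypes
likelihood(ped, map, obs$genotypes,  "genotype")
#> [1] 3.051758e-05
#> attr(,"loglik")
#> [1] -10.39721
likelihood(ped, map, obs$haplotypes, "haplotype")
#> [1] 3.183868e-06
#> attr(,"loglik")
#> [1] -12.65741

# Posterior of the recombination count in the central interval,
# compared with the simulated truth
fb <- forward_backward(ped, map, obs$haplotypes, "haplotype")
recombination_distribution(fb, interval = 2)$pmf
#>            0            1            2            3            4
#> 4.686208e-01 4.228157e-01 1.044323e-01 4.087370e-03 4.379325e-05
sim$true_recomb[2]
#> [1] 0

# Minimum-recombination count for the genotype data
min_recombination(ped, map, obs$genotypes, "genotype")$count
#> [1] 0

# Map the genotyped instance to a haplotyped one (proxy families)
red <- build_proxy_pedigree(ped, obs$genotypes)
nrow(red$pedigree)                 # 5 original + 5 per genotyped individual
#> [1] 20
length(typed_ids(red$haplotypes))  # 5 haplotyped proxies per genotyped one
#> [1] 15
min_recomb_offset(obs$genotypes)   # the additive offset of Lemma 1
#> [1] 10
```

## Main entry points

| Task | Function |
|---|---|
| Build/validate a pedigree | `pedigree()`, `validate_pedigree()` |
| Marker map | `marker_map()` |
| Observation tables | `genotype_table()`, `haplotype_table()` |
| Likelihood (general HMM) | `likelihood()`, `forward_backward()` |
| Minimum recombinations | `min_recombination()` |
| Most probable inheritance path | `max_probability()` |
| Recombination-count posterior | `recombination_distribution()` |
| Genotype-to-haplotype reduction | `build_proxy_pedigree()`, `min_recomb_offset()`, `proxy_constant()`, `verify_proportionality()` |
| Fast fully-haplotyped algorithms | `fully_typed_likelihood()`, `fully_typed_min_recombination()` |
| Trio special case (4-state HMM) | `trio_likelihood()`, `trio_min_recombinations()` |
| Simulation | `default_scenario()`, `sim_gene_drop()`, `mask_data()` |
| Accuracy experiments | `run_accuracy_experiment()`, `recomb_accuracy()` |
| Text file I/O | `read_pedigree()`, `read_marker_map()`, `read_genotype_table()`, `read_haplotype_table()` and the matching writers |

## Command-line interface

A thin CLI lives at `inst/cli/pedhap.R` (after installation:
`system.file("cli", "pedhap.R", package = "pedhap")`). All commands
print JSON to stdout.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pedhap.R",package="pedhap"))')" \
  likelihood --pedigree ped.txt --markers map.tsv --data hap.tsv --kind haplotype
```

Subcommands: `reduce`, `likelihood`, `minrecomb`, `maxprob`,
`recomb-dist`, `simulate`, `experiment`. Run any subcommand without
arguments to see its options.

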