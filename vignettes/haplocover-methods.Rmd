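---
title: "Allocating low-coverage sequencing across population haplotypes: model and methods"
author: "haploCover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allocating low-coverage sequencing across population haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploCover)
```

# The allocation model

## Haplotypes, slots and expected coverage

The unit of analysis is the **core haplotype**: within a window ("core")
of `m` consecutive markers on one chromosome, each phased gamete carries
one allele string, and identical strings define one haplotype. A
sequencing design is a **set of slots**, each slot being 1x sequencing of
one individual; an individual holding `n` slots is sequenced at `n`x. The
number of slots is `floor(budget / costPer1x)`; because library
preparation also costs money, a feasible design usually leaves some slots
empty.

Two simplifying assumptions connect slots to haplotype coverage, and both
are assumptions of the score function itself rather than claims about
sequencers: coverage is uniform along the genome, and each 1x of an
individual reads either the paternal or the maternal gamete with
probability 0.5. Under them, a haplotype whose carriers jointly hold
`HapCount` slot-copies (one per slot of each carrier, per carried copy, so
a homozygous core contributes two per slot) has expected coverage
`HapCount / 2`, and reaching a target coverage `T` requires
`HapCount >= 2T`. All evaluation in the package uses this
expected-coverage model; no stochastic read-sampling model is layered on
top, because the optimisation criterion is defined in the same units.

## The coverage-balancing score

While the set is being built, haplotype `h` scores

$$\mathrm{Score}(h) = \begin{cases}
\exp\!\left(\left(\dfrac{\mathrm{HapCount}_h}{2T-1}\right)^{2}\right) &
\mathrm{HapCount}_h < 2T,\\[4pt]
0 & \mathrm{HapCount}_h \ge 2T.
\end{cases}$$

Every targeted haplotype starts at score 1, rises convexly to `e` at one
copy short of the requirement, and drops to zero once covered. The greedy
step adds, to the first empty slot, the individual maximising the sum of
its carried haplotypes' scores; the convex rise makes the algorithm
finish haplotypes it has started (suppressing the under-sequenced
fraction), and the zero cap stops over-sequencing. Pre-existing sequence
data enters simply as a nonzero starting `HapCount`.

The comparison methods differ only in the per-haplotype score: **IWS**
uses the fixed population-frequency parabola $(1-f)^2$, zeroed at the
same `HapCount >= 2T` cap (the original formulation additionally targets
only haplotypes observed homozygous and stops after the initial set);
**random** ignores scores and fills affordable slots uniformly.

## Refinement

Refinement repeats, for a configured number of rounds: remove the
occupants of `exchangesPerRound` randomly chosen filled slots (an
individual that loses all its slots frees its library cost), refill by
the greedy rule, and accept the exchange iff the percentage of targeted
unique haplotypes with `HapCount >= 2T` did not decrease. The incumbent
metric is therefore non-decreasing by construction, and the same metric
function is used by `summarizeCoverage()`, so evaluation and acceptance
cannot drift apart. Setting `exchangesPerRound` to the whole set size
degenerates, intentionally, into best-of-`k` independent fresh
selections.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `targetCov` | — | x | coverage a consensus haplotype needs; the cap is always `2*targetCov` slot-copies |
| `libraryCost`, `costPer1x` | 40, 80 | currency | linear cost model; a `costHook(nIndividuals, totalCoverage)` replaces it for non-linear pricing |
| `maxIndividualCoverage` | `2*targetCov` | x | optional cap forcing larger, shallower sets; when it binds, haplotypes with population count below `ceiling(2T / cap)` cannot reach the target and are pre-excluded from targeting |
| `exchangeRounds`, `exchangesPerRound` | 100, 10 | — | refinement effort and mobility; few large exchanges approximate restarts, many small ones local search |
| `rareCountThreshold` | 2 | count | "rare" = singletons and doubletons |
| `flankCount`, `nComb` | 2, 3 | count | flanking filter: both flanks must have counts `> flankCount` and the exact (left, right) flanking pair must be carried by `< nComb` gametes |

# Design choices where the procedure was genuinely open

* **Mismatch clustering.** When `maxMismatches > 0`, a gamete string joins
  the lowest-ID existing haplotype whose *founding representative* is
  within the threshold, else founds a new haplotype. Comparing against a
  representative rather than all members keeps assignment deterministic
  and order-stable; gametes are scanned individual-by-individual,
  paternal before maternal.
* **Missing data.** Any missing allele inside a gamete-core yields a
  missing assignment; partial matching is not attempted, since upstream
  phasing tools already gate on the fraction of phased data. A missing
  flanking assignment fails the flanking filter's conditions for that
  carrier.
* **Unaffordable top scorers are skipped**, not terminal: selection
  continues with the next-best affordable candidate, and stops only when
  no candidate is affordable, all slots are filled, or every candidate's
  score is zero. The last case is what leaves the original
  homozygous-only IWS with unspent budget.
* **Ties** for the maximum score are broken uniformly at random from R's
  global RNG stream; callers `set.seed()` for reproducibility, and
  `runScenario()` spawns per-repetition child seeds from its master seed.
  With no prior data all scores start equal, so the first pick is a
  random individual among those carrying the most non-missing targeted
  copies — which is the argmax, not a special case.
* **Refill order** uses the lowest-index empty slots; slot identity
  carries no meaning beyond bookkeeping, so this is a determinism choice.
* **Exchanges sample slots, not individuals**: an individual holding
  several slots can lose only some of them, which is how refinement
  reduces an individual's coverage without evicting it.
* **Prior coverage** adds to `HapCount` but consumes no budget; by
  default a newly selected individual is charged library preparation even
  if it was sequenced before (conservative), unless listed in
  `priorLibraryFree`.
* **The flanking-pair count is per gamete**, including the carrier
  itself, because the combination of flanking haplotypes is
  phase-specific; an option counts distinct individuals instead. The pair
  is counted irrespective of the centre haplotype. For a doubleton, the
  conditions must hold for *both* carrier gametes — one non-mosaic
  occurrence already suggests a phasing error or an unrelated genome.
* **Percentages** are over targeted unique haplotypes;
  `totalPctWeighted` additionally weights each targeted haplotype by its
  population count, measuring covered haplotype *mass*. Coverage
  histograms use half-x bins with a separate exact-zero bin.
* Scores are accumulated in double precision with no rounding; budget
  comparisons allow a 1e-9 absolute slack so exact-budget designs are
  feasible.

# The simulator: what it emulates, and what it does not

`simulatePopulation()` gene-drops core-level haplotypes through a
structured pedigree: discrete generations, equal sex ratio, truncation
selection of the top sires on a heritable polygenic value (parent average
plus Gaussian noise, founders standard normal), all females used. Two
recombination processes act per meiosis, both interference-free: a
source-strand switch between adjacent cores (probability `recombProb`,
default 0.1 — ten cores spanning a ~100 cM chromosome) and a crossover
*inside* a core (probability `mosaicProb` per core), which creates a
novel haplotype that is a mosaic of the two parental haplotypes at that
core and is exactly the kind of rare recombinant the flanking filter is
designed to keep.

Founder gametes draw their haplotype at each core from a pool of
`nFounderHaplotypes` with symmetric-Dirichlet frequencies
(`founderConcentration`), independently across cores, so founder
chromosomes share a haplotype at one core without necessarily sharing it
at the next — mimicking how genealogies change along a chromosome in
coalescent-derived data. This independence matters: if founder identity
persisted across whole chromosomes, rare haplotypes would concentrate in
a handful of relatives and deep-sequencing those few individuals would
dominate every allocation strategy, which is not the structure of real
phased libraries.

The defaults (`founderConcentration = 0.01`, `mosaicProb = 0.004`) were
fixed once so that the default population (15 generations of 1000, 25
sires, 10 chromosomes x 10 cores) shows the right-skewed spectrum
reported for phased livestock haplotype libraries — on the order of a
hundred haplotypes per core with roughly a third singletons and a tenth
doubletons — and were not revisited afterwards. The simulator does *not*
model nucleotide-level sequence, mutation, genotyping error, QTN effects
or realistic linkage maps, and no claim is made that its frequency
spectrum matches any particular dataset exactly. Passing tests on these
populations demonstrate the allocation machinery under a realistic
*shape* of haplotype sharing; they do not certify performance numbers for
any real population, where relatedness structure, core length and
phasing quality all shift the absolute percentages.

`renderMarkerAlleles()` draws a distinct random allele string per founder
haplotype per core (mosaic haplotypes are rendered by splitting their
parents' strings at a breakpoint chosen to keep strings distinct), which
makes the simulate → render → `buildLibrary()` round trip exact and is
how the library-construction code is validated end to end.

# Degenerate inputs and numerical corner cases

Empty populations, core maps that overrun the marker map, duplicate
individual IDs, allele codes outside {0, 1, 9} and ragged genotype rows
are rejected with informative errors rather than coerced. Chromosomes
shorter than one core are dropped by `makeCoreMap()`; single-core
chromosomes make all their rare haplotypes fail the flanking filter's
interior-core condition. `exchangesPerRound` larger than the number of
filled slots is clipped with a warning. An all-capped score state stops
selection with slots left empty rather than forcing useless additions.

# Problem sizes used in the shipped checks

The test suite and the acceptance script are sized for a single desktop
CPU: oracle comparisons run on populations of 10–80 individuals with 2–6
cores; the refinement-monotonicity and method-ordering checks use a
simulated population of 1500 individuals (15 generations of 100, 5
sires, 2 chromosomes x 10 cores) with a budget of 18,000 units — 10% of
the cost of sequencing everyone at 1x — a 10x target, 10 repetitions,
and 100–1000 exchange rounds of 10 slots. At these sizes the full suite
completes in about a minute. The published experiments behind the method
used populations an order of magnitude larger; the directional claims
(method ordering, suppression of the under-sequenced fraction,
monotone refinement) are scale-stable and are what the checks assert,
while absolute percentages are regime-dependent and are not asserted.

# Known limitations

* The heuristic is greedy with local exchange refinement; no optimality
  gap is computed and no integer-programming formulation is attempted.
* The 0.5-per-gamete expected-coverage model ignores coverage variation
  along the genome and between alleles.
* Haplotypes are marker-defined: haplotypes identical on the array may
  hide multiple sequence-level haplotypes; resolving them after
  sequencing is out of scope.
* The rare-haplotype filter directs resources; it is not a recombination
  detector, and it deliberately drops rare haplotypes at chromosome ends
  where flanking evidence is one-sided.
* A secondary, lower target coverage for rare haplotypes is a natural
  extension the package does not implement.
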