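---
title: "Thermodynamic probe-set design for smRNA-FISH: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic probe-set design for smRNA-FISH: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishprobes)
```

Single-molecule RNA FISH counts transcripts as diffraction-limited spots
formed by tens of fluorophore-carrying DNA oligos hybridized along one RNA.
A probe set succeeds when its probes bind the intended transcript with
near-certain occupancy while binding everything else in the transcriptome as
little as possible; off-target hybridization raises background and, when
several probes co-occupy the same off-target molecule, produces
false-positive spots. `fishprobes` designs and evaluates such probe sets
from first principles: it enumerates every place each candidate oligo can
hybridize, converts each putative duplex into a dissociation constant with a
nearest-neighbor thermodynamic model, solves the coupled binding
equilibrium of all probes, their secondary structures and all their sites,
and summarises the result as molecule-count spectra a microscopist can
reason about.

## The reaction model

Three reaction classes compete for each probe: self-hybridization (hairpin
stems within the oligo), cross-dimerization between two probes of the set,
and hybridization to a transcript site. For each interacting pair, all
binding configurations $l$ contribute to one bound-state partition function,

$$K_a = \sum_l \exp\left(-\Delta G^\circ_l / RT\right), \qquad K_d = 1/K_a,$$

so stronger or more numerous configurations always mean a smaller
dissociation constant and more binding. (The configuration sum is sometimes
written directly as a "dissociation constant"; we invert it so that the
mass-action relations below keep their conventional form and monotonicity.)

At steady state the free concentrations obey the mass-action relations
$C^{self}_i = C^{free}_i/K^{self}_i$,
$C^{cross}_{ij} = C^{free}_i C^{free}_j / K^{cross}_{ij}$ and
$C^{bound}_{ijs} = C^{free}_{T_{js}} C^{free}_i / K_{ijs}$, with a parity
coefficient $\alpha_{ij}$ (2 when $i=j$, else 1) accounting for the two
probe copies a homodimer consumes. Eliminating the free site concentration
through its own balance gives one recursion per probe,

$$C^{free}_i = \frac{C^{tot}_i}{1 + \dfrac{1}{K^{self}_i}
  + \sum_j \alpha_{ij}\dfrac{C^{free}_j}{K^{cross}_{ij}}
  + \sum_{j,s} \dfrac{C^{tot}_{T_{js}}}
      {K_{ijs}\left(1 + \sum_{i'} C^{free}_{i'}/K_{i'js}\right)}},$$

which `solve_equilibrium()` iterates as a damped fixed point (damping 0.5,
relative tolerance $10^{-12}$, at most $10^4$ iterations) starting from
`free = total`. If the Picard iteration has not converged after $10^3$
iterations, a damped Newton iteration with a finite-difference Jacobian
takes over; iterates are kept positive by step halving. In practice the
fixed point converges in tens of iterations because probes are typically in
large excess over targets. The unit tests check the solution against an
independent Newton root-finder applied to the *full* system (free probes
and free sites as unknowns) and verify that both mass balances close to
$10^{-8}$ relative.

Transcript abundance enters as RNA copies per cell (nTPM is read as
copies/cell) and is converted to molarity by dividing by the volume of a
sphere of radius 10 um — about a Jurkat cell — times Avogadro's number:
one copy per cell is $\approx 3.96\times10^{-13}$ M. The on/off-target
molecule-count spectra below are reported per cell, so this volume factor
enters only through the equilibrium solve and cancels out of the spectra;
this keeps the counts well-defined whichever unit convention one prefers
for the prefactor.

## From occupancies to specificity

A site $s$ on transcript $j$ is bound with probability

$$p_{js} = \frac{\sum_i C^{free}_i/K_{ijs}}{1 + \sum_i C^{free}_i/K_{ijs}}.$$

Sites on one transcript are independent given the free concentrations, so
the number of probes bound to a transcript follows a Poisson-Binomial
distribution over its sites. `bound_count_distribution()` expands the
probability-generating-function product by iterated convolution, which is
numerically stable and exactly equivalent — the tests verify agreement with
exhaustive $2^N$ enumeration (to $10^{-12}$, $N \le 12$) and with the
generating function evaluated at roots of unity and inverted by DFT
($N \le 6$).

Weighting each transcript's distribution by its expression gives the
expected number of on-target molecules with $n$ probes bound, $N_{on}(n)$,
and likewise $N_{off}(n)$ over off-targets. Their summary is the
**specificity load**

$$\mathrm{load} = \frac{\sum_{n\ge1} n\,N_{off}(n)}
  {\sum_n n\,N_{on}(n) \,/\, \sum_n N_{on}(n)},$$

the number of probes bound to off-targets per mean probe bound per
on-target molecule. Per-probe responsibility for off-target signal is
attributed in proportion to each probe's term $C^{free}_i/K_{ijs}$ in the
site occupancy — the natural decomposition of the occupancy numerator;
`identify_problem_probes()` additionally ranks probes by the leave-one-out
reduction in $\sum_{n\ge2} N_{off}(n)$, the off-targets carrying two or
more probes (the ones bright enough to masquerade as spots).

## Off-target enumeration

Candidate probes are every antisense 20-mer along the target (no GC or Tm
pre-filter — ranking is global, and windows containing N are skipped).
Hybridization sites are found by seed-and-extend: exact 7-mers anchor a
banded Smith-Waterman extension (reward +1, mismatch −3, affine gaps
open 5 / extend 2, implemented in C++) of the probe's binding-site sequence
against the sense transcript, and alignments with fewer than 15 matched
nucleotides are discarded — shorter duplexes have negligible occupancy at
working conditions, which also makes an E-value cutoff redundant at this
scale. Only RNA is searched. The tests verify that on fixtures under 2 kb
the retained hit set equals a brute-force full Smith-Waterman over every
probe-transcript pair (via an independent aligner) and that planted
complements are recovered exactly at and only at the 15-nt threshold.

Overlapping hit spans on one transcript are clustered by single linkage
into non-overlapping sites (the clustering rule is our choice; adjacent
but non-overlapping spans stay separate), every member alignment becoming
one binding configuration of its site. Probes with any retained hit on an
rRNA-biotype transcript are excluded outright: rRNA abundance makes even
marginal binding costly.

## Duplex thermodynamics

Energies come from the unified DNA/DNA nearest-neighbor parameter set
(shipped as a versioned CSV): an alignment is split at mismatches and gaps
into perfectly matched segments; segments of at least 2 bp contribute their
stack enthalpies and entropies, one duplex-initiation term is applied per
duplex plus a terminal A·T penalty per closing A·T pair, and the entropy
receives the sodium correction $\Delta S + 0.368\,N_{stacks}\ln[\mathrm{Na}^+]$.
Mismatch stacking is deliberately not modelled — mismatched columns simply
break segments — which underestimates some off-target affinities; the
design errs on the side of counting such sites at reduced strength rather
than modelling mismatch thermodynamics it cannot validate at this scale.
Gapped columns likewise carry no loop energy. Hairpin stems require at
least 3 consecutive pairs separated by a minimum loop of 3 nt (the
shortest sterically plausible loop); the 5 best stems are kept as
self-hybridization configurations (the count is configurable — suboptimal
stems beyond the fifth contribute negligibly to the partition function of a
20-mer). Cross-dimers are evaluated in both strand orientations
(antiparallel and parallel), each orientation contributing its best
ungapped pairing; parallel-duplex stacks are approximated with the
antiparallel parameter table, a deliberate simplification for an
interaction class that is almost always energetically irrelevant. No
symmetry correction is applied to self-complementary homodimers;
homodimer stoichiometry is instead carried exactly by the parity
coefficient.

## Selection

Candidates are ordered by **prioritization rank**: first by number of
off-target sites (ascending; optionally expression-weighted, default off —
the equal-expression assumption is the conventional design condition),
then by the energy gap
$\Delta G_{on} - (\sum \Delta G_{off} + \Delta G_{self} + \Delta G_{cross})$
(ascending: a more negative on-target energy and weaker competing
interactions rank better), with the target start coordinate as a final
deterministic tie-break (the rank must totally order candidates for
byte-reproducible designs). Selection proceeds in two phases — probes with
no off-targets first, the rest afterwards — each phase cycling: take the
top-ranked candidate; permanently remove candidates violating the minimum
spacing (3 nt) against any selection; fold each remaining candidate's best
cross-dimer energy against the new selection into its accrued
secondary-structure term and re-rank. Off-target counting is site-resolved
(a transcript carrying two sites counts twice), matching the site-resolved
equilibrium model. Overlap removal is permanent rather than per-iteration,
and the spacing constraint is what defines "overlap".

`refine_probe_set()` applies the same evaluation machinery to an existing
probe set without re-tiling, ranking probes by their off-target
contribution and optionally dropping the worst offenders.

## Synthetic fixtures: what they emulate and what they do not

The generator builds the conditions under which a hard gene challenges
probe design: the canned benchmark scenario has one ~1.5 kb mRNA target
(within the 500-3000 nt hard-gene window) with two isoforms (fewer than
five, sharing a 70% 3' block), thirty random decoys of 400-800 nt plus one
rRNA decoy, eight planted off-target homologies of 15-20 nt — one on the
rRNA decoy — and log-normal expression (meanlog log 60, sdlog 1, a typical
moderately expressed gene with realistic spread) across three cell-line
contexts with 50-fold elevated rRNA. Plants are exact sense copies of
target sub-windows; the generator forces the five bases flanking each
plant to mismatch the target continuation (so sub-threshold plants cannot
be extended past the retention cutoff by chance alignment) and re-rolls
any decoy sharing a 12-mer with the target outside a planted region, which
keeps the ground-truth manifest exact at fixture scale.

What the fixtures do **not** emulate: the sequence-composition structure of
real transcriptomes (repeat families, low-complexity tracts, homopolymer
runs), genome-scale chance-homology spectra, splice-graph isoform
structure, RNA secondary structure occluding sites, and realistic
co-expression covariance. A green test suite therefore demonstrates that
the algorithms are implemented correctly and behave as specified under
controlled homology and expression — not that a probe set designed against
a real genome will show any particular wet-lab performance.

## Defaults and problem sizes

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| probe_length | 20 | nt | standard short-probe smFISH design |
| min_spacing | 3 | nt | minimum gap between adjacent probes |
| min_match | 15 | nt | retention threshold for hybridization-relevant alignments |
| word_size | 7 | nt | seed size for the k-mer index |
| temperature_C | 37 | °C | hybridization temperature |
| sodium_M | 0.3 | M | monovalent salt of the hybridization buffer |
| probe_conc_nM | 5 | nM | per-probe total; typical working dilution scale (stock molarity is protocol-dependent, so this is configurable and logged in every report) |
| cell_radius_um | 10 | μm | spherical cell approximating a Jurkat cell |
| max_probes | 48 | – | a standard panel size |
| expression_mode | equal | – | the conventional design assumption; mean-average and cell-line modes available |

Tests and the acceptance script run at desk scale by design: equilibrium
oracle checks use up to 4 probes x 5 sites over 50 seeded instances,
alignment brute-force checks use sub-2-kb transcriptomes, and the
end-to-end benchmark designs ~1,480 candidates against a ~19 kb synthetic
transcriptome — sizes chosen so every quantity can be verified against an
independent oracle, with the full pipeline exercised unchanged.

## Known limitations

Besides the fixture caveats above: binding is equilibrium-only (no
kinetics, no toehold displacement, no partial binding of overlapping
probes); formamide is not modelled; DNA targets and nascent/intronic RNA
are out of scope; mismatch and loop thermodynamics are simplified as
described; and under the equal-expression mode the off-target spectra are
per-copy rates, not cell-type predictions. When expression tables are
supplied, absent transcripts are treated as unexpressed (zero) with a
logged warning.
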