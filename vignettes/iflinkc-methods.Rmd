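---
title: "In silico iterative functional linker cloning: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico iterative functional linker cloning: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iflinkc)
```

This vignette explains the science implemented by `iflinkc`: the cloning
chemistry it simulates, the combinatorial and statistical models behind the
library planner, the kinetic and binding models behind the screening
analytics, and the design choices made where the underlying protocol leaves
the DNA-level details open.

## The cloning chemistry

iFLinkC builds fusion proteins by iterating one elementary cycle. Each part
(a functional domain or a peptide linker) lives in a circular entry plasmid
whose insert is flanked by two type IIS restriction enzymes — BtsI
(GCAGTG(2/0)) upstream and BsrDI (GCAATG(2/0), on the bottom strand)
downstream — plus single EcoRI and SpeI sites in the backbone. BtsI and
BsrDI cut outside their recognition sequences and both leave 2-nt 3′
overhangs; EcoRI and SpeI leave 4-nt 5′ overhangs. One cycle digests the
*acceptor* plasmid with BsrDI + a flank enzyme and the *donor* with BtsI +
the same flank enzyme, gel-purifies one fragment from each, and ligates the
two fragments into a circle. The product carries the fused insert between a
fresh BtsI/BsrDI pair, so it is immediately usable in the next cycle — the
defining iterability property, tested explicitly over ten consecutive
rounds.

### The junction convention

The protocol specifies the protein-level outcome — domains joined through a
bridging Gly, with printed linker lengths that already include their two
terminal Gly residues — but not the vector sequences, so the DNA-level
bookkeeping is a package convention:

```
cassette:  GCAGTG · GT · core · GGT · CATTGC
                └┬─┘        └┬┘
        junction Gly codons: the last G of the BtsI site starts a GGT
        codon whose "GT" is the 2-nt overhang
```

`core` of a linker is its coding DNA minus the first and last codon; `core`
of a domain is its full coding DNA. Consequences, all enforced by
invariants and tests:

* every ligation junction's 2-nt overhang lies inside a Gly codon (GGT by
  default, configurable via `junction_codon`);
* a domain–domain cycle inserts exactly one bridging Gly — this *is* the
  single-"G" catalogue linker, which therefore has no entry plasmid of its
  own;
* a stored linker shares its printed terminal Gly residues with the
  junctions, so an alternating domain–linker fusion has protein length
  Σ(domain lengths) + Σ(printed linker lengths), with no hidden residues;
* the rare linker–linker fusion shares one Gly between the two linkers
  (`chain_protein()` documents and implements this merge).

The orientation of the two type IIS sites relative to the insert is not
derivable from the protocol text; the package fixes BtsI upstream / BsrDI
downstream. The non-palindromic overhang (GT/AC) then enforces insert
orientation at every ligation.

### Sequence representation

A molecule is stored as its physical top strand plus typed ends; overhang
nucleotides carried only by the bottom strand live in the end objects. Two
properties follow with no special cases: top-strand length is exactly
conserved by digestion (each overhang counted once), and ligation is string
concatenation. Circular equality is defined by the lexicographically
minimal rotation; digestion across the origin scans the doubled sequence.
Partial digestion, star activity and methylation are deliberately not
modelled — the workflow assumes complete digestion followed by gel
purification — and cut sites closer together than their staggered spans
raise a degenerate-input error rather than producing physically impossible
fragments.

### Gel selection and dephosphorylation

`choose_enzyme_pair()` picks the shared flank enzyme (SpeI or EcoRI) so
that in both digests the wanted fragment differs from its sibling by at
least the resolvable-size ratio (default 20%; the protocol gives no number,
so it is a configurable package default). The backbone-bearing acceptor
fragment is dephosphorylated by default, mirroring the use of alkaline
phosphatase to suppress backbone self-ligation: ligation requires at least
one phosphorylated partner per junction, so a dephosphorylated–
dephosphorylated junction is rejected.

## Parts and reverse translation

The bundled catalogue carries the 15 linker elements with their printed
peptide sequences, lengths and flexibility classes (4 short, 4 flexible,
4 rigid, 3 semi-flexible); functional domains ship as length-only stubs
(FRB 91 aa, FN3 92, ePDZ-B1 97, FKBP12 106, MBP fusion 398, TVMV protease
222) because their coding sequences are not part of the catalogue — fixture
generators create random stand-ins of the right lengths, clearly labelled
synthetic.

Linker DNA is synthesized in silico under a codon policy: the most
preferred E. coli K-12 codon per residue, with a deterministic depth-first
search (left to right, preference order, backtracking) that guarantees the
result contains no BsrDI/BtsI/EcoRI/SpeI site on either strand and no
direct repeat longer than 8 nt — the practical constraints for synthesizing
and cloning GC-rich, repetitive linker DNA. Two deliberate choices: GGT
heads the Gly codon list (GGC is marginally more frequent in K-12) so that
the preferred Gly codon coincides with the junction codon, and the 8-nt
repeat threshold is configurable (`codon_policy(max_repeat=)`). Because
none of the four forbidden motifs contains "GGT" as a substring, a part
whose DNA is site-free when flanked by GGT on both sides can never create a
site across *any* junction — this lemma is what makes per-part validation
(`validate_part()`, `junction_clean`) sufficient for whole-library frame
safety, which the test suite nevertheless verifies end-to-end for every
catalogue linker.

## Library planning and coverage

Enumeration is the slot-major Cartesian product of the per-slot candidate
sets; `theoretical_diversity()` is the product of their sizes (7 × 15 × 7 =
735 for the three-linker affinity-clamp library), and designs with
identical protein sequences are additionally reported deduplicated.
Scheduling uses balanced pairwise pairing with leftmost-first tie-breaking:
n parts fuse in ⌈log₂ n⌉ parallel rounds, e.g. four domains + three linkers
(seven parts) in three rounds.

Screening coverage uses classical occupancy statistics under equal sampling
probability per variant (no ligation bias is modelled; a weight vector hook
is left for future bias models): the expected number of distinct variants
among N clones from diversity D is `D(1 − (1 − 1/D)^N)`, computed via
`expm1/log1p` for numerical stability and verified against a Monte-Carlo
multinomial oracle to within 3 standard errors across an (N, D) grid.
`clones_for_coverage()` inverts the curve exactly by closed form plus
integer verification. The "saturating" label uses a 95% expected-coverage
threshold (configurable); screening 467 of 735 gives 47% expected coverage
and is accordingly labelled sub-saturating.

## Screening analytics

**Initial rates.** Protease activity is the slope of the fluorescence
trace while substrate is in excess. The window is selected
deterministically: starting at the first point above background + 3
background-SDs, the longest prefix of ≥5 points with r² ≥ 0.99 is taken,
then trailing points that depart from the remaining window's fit by more
than 5 within-window residual SDs are trimmed (this removes plateau onset
exactly on clean traces). All thresholds are arguments. When no window
qualifies the estimate is still returned, flagged, with a warning — never
silently.

**Fold changes.** Replicate rates are averaged (mean of rates, not of
traces) and the reported ratio is oriented so it is always ≥ 1: fold
induction for ON-switches, fold repression for OFF-switches. The SE
propagates the regression SEs of the means with relative errors added in
quadrature; a replicate-scatter SE is the natural alternative when many
replicates exist, but duplicate measurements are the norm here. When the
OFF-state rate is within 2 SE of the background rate the ratio is reported
as a lower bound (">X-fold"), computed against denominator + 2 SE.

**Dose–response fits.** Activation follows
`v(L) = v0 + (vmax − v0) f_bound(L)` and inhibition
`v(I) = v0 (1 − f_inhibited(I))`. The binding fraction is the single-site
hyperbola `L/(K + L)` by default; when the fitted constant comes within an
order of magnitude of the protein concentration (E ≥ K/10) the quadratic
Morrison (tight-binding) isotherm replaces it and the fit is rerun — the
model id in every `iflc_fit` records which form produced the estimate, so
alternative forms can be swapped in and compared. The least squares are
weighted by inverse squared signal because plate-reader rate noise scales
with the signal (constant CV); with 2% multiplicative noise this makes the
reported SEs consistent (≈95% coverage of ±2 SE intervals in the recovery
simulations). Fits fail loudly (`iflc_fit_error`) on non-convergence, a
relative SE above 100%, an estimate far above the dosed range (no curvature
— the non-identifiable design), or an amplitude indistinguishable from
zero. `ic50()` root-finds the fitted curve for the half-inhibition dose,
which equals K_i for the hyperbolic model and exceeds it by ≈E/2 in the
tight regime.

## What the synthetic data emulate — and what they do not

The fixture generators reproduce the *structure* of the experimental
inputs: entry/destination plasmids with correct site architecture (~2.5 kb,
segments 400/700/1400 nt around the cassette, placed asymmetrically so both
flank digests resolve on a gel), domain stand-ins of the published lengths,
linear-then-plateau kinetic traces with multiplicative Gaussian noise
(default SD 2%, matching duplicate-level scatter of plate reads), and dose
series on the package's own binding models over the 50 nM – 1 mM titration
range. They do not emulate expression-level variation between clones,
lysate matrix effects, inner-filter corrections, ligation bias, or
incomplete digestion — so green tests demonstrate the correctness of the
computational pipeline at the stated noise level, not robustness to every
failure mode of real screens. Every generator draws from a named stream
derived from its seed and arguments, so adding a generator never shifts an
existing fixture.

## Problem sizes and numerical choices

The test suite uses sizes chosen to exercise the asymptotics while staying
desk-scale: 1000 random plasmids (300–900 bp) for the digest–ligate
round-trip identity; ten consecutive assembly cycles for iterability; all
15 catalogue linkers between two fixture domains for frame safety; 2 × 10⁴
Monte-Carlo replicates per occupancy grid point (10⁵ for the 467-of-735
flagship comparison); and 50 replicates per constant for the parameter-
recovery grid over K ∈ {20 nM, 3 µM, 4.5 µM, 186 µM, 196 µM} at 2% noise
with 12 doses titrated over K/30–30K (a recovery simulation doses around
the constant it probes; the fixed 50 nM–1 mM range is used where the
titration itself is the object of study). Acceptance recovery criteria use
noiseless series, where the fits return the generating constants to ≈10
significant digits; the 5% tolerance covers model-switch and optimizer
slack.

## Known limitations

* GenBank I/O is a minimal LOCUS/FEATURES/ORIGIN dialect — sufficient for
  byte-stable round trips of the package's own records, not a general
  parser for arbitrary records from other software.
* The entry backbones are synthetic stand-ins; real pL2/pFD vectors would
  change fragment sizes (and hence `choose_enzyme_pair`'s flank choices)
  but no engine logic, which is backbone-agnostic.
* Ligation is all-or-nothing per the compatibility rules; no
  thermodynamic efficiency, concatemer kinetics or transformation-
  efficiency modelling.
* The Michaelis–Menten layer of the protease assay is folded into the
  apparent constants; substrate-depletion effects beyond the plateau cap
  are not modelled.
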