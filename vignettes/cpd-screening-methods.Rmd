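---
title: "Methods: screening compensated pathogenic deviations in the mitochondrial ribosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening compensated pathogenic deviations in the mitochondrial ribosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdscreen)
```

## The screening idea

Some homoplasmic mitochondrial DNA mutations that cause disease in humans
— the 12S rRNA decoding-site transitions m.1494C>T and m.1555A>G behind
aminoglycoside-induced and non-syndromic hearing loss are the motivating
case — show incomplete penetrance: many carriers never develop the
phenotype. One way to hunt for the modifier factors responsible is
evolutionary. If another species carries the human *pathogenic* allele as
its fixed wild type and is healthy, that allele is a **compensated
pathogenic deviation (CPD)**: something else in that species' genome must
suppress the deleterious effect. Finding what changed alongside the CPD —
and *when* — points at candidate modifier genes for the human disease.

`cpdscreen` implements that screen as four composable stages:

1. **CPD calling.** Align orthologous sequences against a designated human
   reference row, map the reference coordinate of the pathogenic site
   (rCRS numbering, e.g. m.1494) to its alignment column, and classify
   every species as wild-type, pathogenic-allele carrier, other, or
   unresolved. Carriers are tallied by clade (family / subfamily / tribe)
   to find lineages where the pathogenic allele is fixed.
2. **Conservation index (CI).** The CI of a position is the percentage of
   aligned sequences carrying the human wild-type state. A pathogenic
   position with CI above the gene average is functionally important; a
   candidate compensatory protein position with *high* CI (i.e. variable
   in only a few lineages) is a better compensation candidate than a
   freely drifting one. Sets of positions are compared by their mean CI
   with an unpaired two-tailed Student *t*-test.
3. **Structural proximity.** Candidate compensatory residues in a
   ribosomal protein are only plausible modifiers if they sit near the
   rRNA site in the assembled ribosome. Positions are mapped onto a
   bacterial small-subunit crystal structure and filtered by minimum
   heavy-atom distance to the target nucleotide (default: strictly less
   than 6 Å).
4. **Fixation dating.** On a dated species tree, a derived allele confined
   to one clade (allowing rare reversions) must have been fixed between
   the clade's **stem age** and **crown age**. Comparing the windows of
   the rRNA allele and the protein allele bounds the time that separated
   the pathogenic fixation from its compensation.

## The worked case the package is built around

The motivating analysis concerns the old world monkeys
(Cercopithecidae): they carry m.1494T — pathogenic in humans — as their
wild type (with a single reverted species, *Papio ursinus*), while their
hearing is normal. In the decoding site, position 1494 faces position
1555: the human wild-type C1494–A1555 pair lacks a Watson–Crick bond, and
either pathogenic transition rebuilds it, making the site more
bacterial-like and aminoglycoside-binding (`wc_pair_status()` implements
exactly this strict complementarity logic; G·U wobble deliberately does
not count). The candidate compensation is MRPS12 p.R68L, a mitoribosomal
decoding-center protein position that is (a) highly conserved in mammals
(CI 90.0%, 63 of 70 species), (b) variable specifically in the Papionini
tribe, and (c) the only candidate position within 6 Å of nucleotide 1494
in the *Thermus thermophilus* small-subunit structure.

On the dated catarrhine tree (`primate_tree_spec()`), with hominoids
splitting from the old world monkey lineage 32 Mya, the Cercopithecidae
crown at 18 Mya, the Cercopithecini–Papionini split at 12 Mya and the
Papionini crown at 8 Mya:

```{r dating}
tt <- make_dated_tree(primate_tree_spec())
f_rna  <- fixation_interval(tt$tree, tt$states$mt1494T,    max_losses = 1)
f_prot <- fixation_interval(tt$tree, tt$states$mrps12_L68, max_losses = 1)
f_rna
f_prot
interval_gap(f_rna, f_prot)
```

The rRNA allele was fixed 32–18 Mya, the protein allele 12–8 Mya, so at
least 6 Myr separate the pathogenic fixation from its compensation — the
pathogenic state survived on its own for millions of years, which is the
interesting evolutionary puzzle the screen surfaces.

## The conservation index: definition and conventions

For reference position $p$ mapping to column $c$ with wild-type state
$w$ (the reference row's own state at $c$),

$$\mathrm{CI}(p) = 100 \cdot \frac{n_\mathrm{match}}{n_\mathrm{total}}$$

where $n_\mathrm{total}$ counts **every non-reference record** and
$n_\mathrm{match}$ those whose state at $c$ equals $w$.

Conventions worth stating because they change the numbers:

* **The reference row is excluded from both counts.** With it included, a
  608-species panel would give 545/609 rather than 544/608; excluding it
  makes the CI a statement about the *other* species.
* **Gaps and N/X stay in the denominator but never match.** A sequence
  with a gap does not harbor the wild-type variant; dropping such
  records from the denominator would inflate CI at poorly covered
  columns. Ambiguity codes beyond N (X for protein) are collapsed to the
  unresolved class at read time, so the denominator has a single
  "unresolved" category.
* **Set means average per-position CIs**, not pooled match counts, so a
  set's mean is exactly the mean of its printed per-position values.
* CI is reported to 1 decimal place; all comparisons use full precision.
* `gene_mean_ci()` iterates over ungapped *reference* positions only;
  columns where the reference is gapped (insertions relative to the
  reference) have no reference coordinate and no defined wild type.

`compare_ci_sets()` uses the classical pooled-variance Student *t*-test
(two-tailed, significance at $p<0.05$) as its default, matching the
era's standard desktop statistics packages; Welch's correction is
available via `var_equal = FALSE`. Identical non-constant sets give
$t = 0, p = 1$; zero pooled variance is an error rather than a silent
`NaN`.

## Fixation dating: the single-gain model

`derived_clade()` implements a Dollo-like parsimony model: **exactly one
gain** of the derived allele, up to `max_losses` subsequent losses
(reversions), and no regain. The gain clade is the MRCA of all derived
tips; inside it, the number of *maximal* subclades whose resolved tips
are all ancestral is the minimum number of losses required (each such
maximal subclade can be explained by one reversion on its stem, and no
single reversion can span two of them, since any clade containing both
also contains a derived tip). If that number exceeds `max_losses` the
reconstruction fails loudly — a non-monophyletic derived state that
would need two independent gains is a different biological story and
should never be silently resolved to one of the clades.

Choices within this model:

* **`max_losses` defaults to 1**: the worked case needs exactly one
  tolerated reversion (*Papio ursinus*), and allowing unbounded losses
  would let any tip distribution collapse to the root.
* **Unknown-state tips are unconstrained**, not treated as ancestral. An
  unsampled subfamily (the Colobinae could not be genotyped for MRPS12)
  must widen uncertainty, not manufacture reversions.
* The fixation window is **[stem age, crown age]** of the gain clade:
  the allele cannot have been fixed before the clade split from its
  sister (it is absent there) nor after the clade's own deepest split
  (all descendants carry it). A gain on the root edge uses the root age
  as its oldest bound; a single-tip gain has a youngest bound of 0.
* `interval_gap()` identifies the earlier interval by its larger oldest
  bound and returns `max(0, earlier.youngest - later.oldest)`; zero
  flags possible overlap rather than a negative "gap".
* Ages are carried as continuous Myr; trees must be ultrametric within a
  relative tolerance of $10^{-6}$ unless explicit tip ages are declared;
  reporting rounds to 1 decimal.

## Structural proximity

`read_structure()` parses wwPDB v3.3 fixed-column files (through
`bio3d`), keeps the highest-occupancy alternate location of each atom and
drops waters. Distances are minimum Euclidean distances over all atom
pairs between two residue selections. Defaults:

* **Heavy atoms only** — crystal structures at ribosome resolutions have
  no modeled hydrogens, so a contact criterion that silently included
  hydrogens would change meaning the moment a model with hydrogens is
  supplied.
* **Strict threshold** (`d < 6` Å, not `<=`), configurable.
* Human-to-bacterial numbering is resolved by global pairwise alignment
  (match +1, mismatch −1, gap open 5, gap extend 1) of the query
  sequence against the chain sequence, unless a curated equivalence
  table is supplied, which overrides alignment entirely; a map covering
  less than half of the query is rejected as low-confidence rather than
  used quietly. Candidates missing from the map are reported as
  `unresolved`, never dropped.
* mmCIF is out of scope; the supported input is the PDB fixed-column
  dialect.

## What the synthetic generators emulate — and what they do not

The screen's reference datasets (hundreds of GenBank/Ensembl orthologs, a
ribosome crystal structure) cannot ship with a package, so `cpdscreen`
generates stand-ins with *exactly specified* structure:

* `make_alignment()` reproduces requested per-column counts
  (matches / others / gaps) on top of an i.i.d. background (default
  match probability 0.9, roughly the gene-wide conservation of a
  mitochondrial rRNA panel). Columns are specified by counts — there is
  **no substitution model and no phylogenetic correlation** between
  records, so generated alignments exercise the counting statistics,
  not the evolutionary realism, of the pipeline. Passing tests on them
  shows the estimators are computed correctly, not that real alignments
  are well behaved (alignment quality, paralogy and coverage gaps remain
  the user's responsibility).
* `make_dated_tree()` builds ultrametric trees with exact named-node
  ages and clade-rule tip states with named exceptions;
  `primate_tree_spec()` encodes the catarrhine case (32/18/12/8 Mya).
  Sister-clade ages not pinned by those published splits (hominoid
  crown 20, Colobinae crown 13, Cercopithecini crown 9, *Macaca* crown
  5 Mya) are plausible round values chosen once; none of them affects
  the stem/crown bounds of the two dated alleles.
* `make_structure()` writes toy PDB files in which each candidate
  residue's closest atom sits exactly at its declared distance from the
  site along an outward ray (guaranteeing no other site atom is
  closer), with remaining atoms strictly farther. Declared distances are
  honored to $10^{-3}$ Å (the PDB format's three-decimal coordinates
  round at $5\times10^{-4}$ per axis).

Every generator draws from its own explicitly seeded stream and restores
the caller's RNG state, so identical specs give byte-identical FASTA /
newick / PDB output.

## Numerical and degenerate-input choices

* Coordinates are 1-based and closed everywhere (m.1494 is the 1494th
  rCRS base); `U` is equated with `T` at read time since rRNA sequences
  appear in both conventions.
* If an alignment's reference state at a site disagrees with the
  declared wild-type allele, the declared site definition wins with a
  warning: the reference row is the coordinate authority, but curated
  site tables may encode historical alleles.
* A clade is "fixed" for the pathogenic allele when at least a
  configurable fraction (default 1.0) of its resolved members carry it;
  the count of exceptions is always reported, so near-fixation (47 of
  48, one reversion) is visible at any threshold.
* Degenerate inputs fail loudly and specifically: ragged alignments,
  missing reference rows, out-of-range positions, empty CI sets, CI
  comparisons with fewer than two values or zero pooled variance,
  negative branch lengths, non-ultrametric trees without declared tip
  ages, empty atom selections, and identical distance selections are
  all distinct errors.

## Verification strategy and problem sizes

The test suite checks every estimator against an independent oracle
implemented a different way: per-column hand tallies for CI and the gene
mean, the textbook pooled-variance formula for the *t*-test, a
brute-force enumeration of all clades (coverage of derived tips plus
exhaustive search over loss-clade combinations) for the single-gain
reconstruction on 1000 random coalescent trees of up to 12 tips, and an
all-pairs scan for minimum distances on 100 random 50-atom selections.
Invariants (permutation and duplication invariance of CI, monotonicity
under adding matching/mismatching records, rigid-motion invariance of
distances, order invariance of verdicts, stem $\ge$ crown) are exercised
as property-style loops under fixed seeds. These sizes keep the full
suite under half a minute while covering the tree shapes and geometries
where the estimators could disagree with brute force.

## Known limitations

* The CI is a plain match percentage; no entropy- or rate-based
  conservation score, and no correction for phylogenetic non-independence
  of the sampled species.
* Single-gain dating is parsimony, not probabilistic ancestral-state
  reconstruction; it reports bounds, not posterior densities, and it
  inherits the supplied tree's ages uncritically.
* The structure stage reports geometric proximity only — no energetics,
  no contact-network analysis — and trusts the user's chain choices.
* The package consumes alignments; it does not compute them, and it does
  not fetch sequences from public databases.
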