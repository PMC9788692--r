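---
title: "Comparing homologous structured-RNA motifs: models and methods"
author: "MotifContrast authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing homologous structured-RNA motifs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MotifContrast)
```

## The problem

Riboswitch variants are homologs of a known riboswitch class whose
binding-pocket nucleotides have changed, usually changing the ligand.
Candidate variants are discovered by comparative genomics as conserved
RNA motifs that resemble a known class but sit upstream of different
genes. Deciding whether a candidate is a genuine variant requires
comparing two multiple alignments of homologous motifs and asking three
questions:

1. Which conserved features (nucleotide identities, structural
   elements) differ *systematically* between the motifs, across phyla?
2. Are the two motifs associated with different downstream gene classes
   and environments?
3. Can new sequences be assigned confidently to one motif or the other,
   given that homology makes the boundary fuzzy?

`MotifContrast` implements this comparison end to end, plus the
quantification of the standard wet-lab assays used to validate such
candidates (in-line probing, transcription termination, acetyl-transfer
calibration). A seeded synthetic-data generator emulates all required
input structure so that every analysis can be exercised and tested
without external data.

## Data model

A `MotifAlignment` is a set of gapped RNA sequences of equal width, a
consensus structure string (`SS_cons`) and per-sequence metadata
(downstream-gene domain, phylum, environment). The `SS_cons` dialect
follows Stockholm/WUSS practice: brackets (`<>`, `()`, `[]`, `{}`) are
nested pairs, matched upper/lower-case letters (`Aa`, `Bb`, ...) are
pseudoknot layers, and `. , _ - : ~` are unpaired. Columns and sequence
positions are 1-based throughout. `T` is normalized to `U` on input;
IUPAC ambiguity codes other than `ACGU-` are kept in the sequences but
counted as gaps by all profile computations (they are rare in curated
alignments and must not skew frequencies silently; a warning reports
them).

Stockholm has no standard tags for gene context or habitat, so the
package defines a documented dialect: `#=GS <id> GENE <domain>`,
`#=GS <id> PHYLUM <name>`, `#=GS <id> ENV <gut|non_gut|unknown>`.
Unknown `#=GS` tags are preserved verbatim.

## Consensus model

`buildConsensus()` summarises an alignment column-wise. Identity
fractions are computed among non-gap residues; the present fraction is
the non-gap proportion. Conservation tiers follow the R2R drawing
convention used throughout the comparative-RNA literature: nucleotide
identity at 97 / 90 / 75 percent and present fraction at
97 / 90 / 75 / 50 percent. A small epsilon (1e-9) guards the threshold
comparisons against floating-point representation error so that a column
at exactly 0.97 lands in the 97 tier.

No sequence weighting is applied: frequencies are unweighted row
proportions. Phylogenetic redundancy can therefore inflate apparent
conservation in real data; the synthetic generator's default
(independent rows) matches this assumption, and a star-tree mode exists
to stress-test the downstream analyses when it is violated.

### Covariation

Consensus pairs are scored with mutual information in bits. For columns
$i, j$, over the rows where both are non-gap (pairwise deletion, which
maximises usable data per pair),

$$\mathrm{MI}(i,j) = \sum_{a,b} p_{ab}\log_2\frac{p_{ab}}{p_a\,p_b},$$

followed by the average product correction
$$\mathrm{APC}(i,j) = \frac{\overline{\mathrm{MI}}(i,\cdot)\,
\overline{\mathrm{MI}}(\cdot,j)}{\overline{\mathrm{MI}}},$$
with the background means taken over *all* column pairs of the
alignment having at least 5 jointly present rows (pairs with fewer rows
have unstable marginals and are excluded; pairs that sparse are also
flagged `low_support` in the output). A pair is called covarying when
`mi_apc_bits` exceeds `tauMI` (default 0.3 bits), at least 90 percent of
jointly present rows form a canonical pair (Watson-Crick or GU), and at
least two distinct canonical pair types occur at frequency 0.05 or
more. This is a deliberately self-contained covariation signal: it is
not a reimplementation of R-scape's G-test statistic, which the
comparative pipeline upstream of this package would normally provide;
the analyses here only consume a binary covariation annotation.

## Mapping two motifs and finding discriminating features

Homologous motifs are compared at *analogous* columns.
`mapColumns()` computes a global profile-profile alignment by dynamic
programming (Gotoh, affine gaps; open -1.0, extend -0.2). The match
score of columns $a, b$ is $\sum_x f_A(x)f_B(x)$ plus a bonus of 0.5
when both columns are paired or both unpaired, so that secondary
structure co-decides the correspondence. Ties are broken toward the
match state, keeping the traceback on the diagonal; the result is
deterministic. When a curated correspondence exists, an anchor map
(two-column TSV) overrides the automatic alignment.

`findDiscriminatingFeatures()` then scans

* **matched columns** for identity contrasts: a nucleotide whose
  frequency is at least `tauHi` in one motif and at most `tauLo` in the
  other is a *strict* contrast (defaults 0.97 / 0.03); 0.90 / 0.10
  grades *high*. These thresholds operationalize "close to 100 percent
  conserved in one motif but never or rarely the same in the other";
  they are exposed as configuration because the cut is a judgement
  call. A column below 50 percent present in either motif is never
  judged on identity — absence and identity change must not be
  confounded; such columns are the business of element detection.
* **maximal runs of unmatched columns** (length >= 4) for structural
  elements present in one motif only. Element presence is
  gap-occupancy-based: the fraction of rows with at least
  `minResidues = 6` residues in the span (the minimal hairpin: 2 bp
  stem + 2 nt loop). Thermodynamic folding is deliberately avoided: an
  extra hairpin manifests in a motif alignment as columns the other
  motif lacks, so occupancy suffices and keeps the package free of a
  folding dependency.

Features are returned sorted by contrast, strict before high by
construction.

## Gene context and environment

`geneFrequencyTable()` counts RNAs per downstream-gene domain and
reports percentages of the *full* motif totals, so unlabeled RNAs
dilute the listed classes (they sum to less than 100 percent when rarer
genes exist). One domain label per RNA is the expected input; semicolon
separated multi-labels are accepted and counted once per label.

`fisherExact2x2()` performs the exact test by full hypergeometric
enumeration. The two-sided p-value is the sum of probabilities of all
tables (with the observed margins) whose probability does not exceed
the observed table's — stated explicitly because two-sided conventions
differ between implementations. The odds ratio is the sample odds ratio
$(ad)/(bc)$, not a conditional MLE. A chi-square with Yates correction
is available behind a flag for large tables. The environment analysis
is a 2x2 of motif gut / non-gut counts against a user-supplied
background of sampled metagenomes; rows labelled `unknown` are
excluded. Published evidence for such enrichments is often qualitative;
the 2x2 formulation is one reasonable formalization, and the background
set is an explicit argument rather than a hidden default for that
reason.

## Classification

`classifySequence()` assigns a sequence to motif A or B:

1. Align the sequence to each consensus model
   (`alignToModel()`; same affine scoring family as the column mapper,
   with the residue-vs-column score equal to the column's identity
   fraction of that residue). Residues aligned between columns are
   dropped from the gapped string and counted as insertions.
2. Score each gapped string against its model's position-specific
   log-odds: $\log_2\frac{f(x)+\alpha}{0.25+\alpha}$ per residue column
   with pseudocount $\alpha = 0.01$ and a uniform background (no
   genomic background composition is assumed); gap columns contribute
   $\log_2\frac{g_c+\alpha}{\bar g+\alpha}$ against the model's mean
   gap frequency.
3. Label by the higher score when the margin $|\Delta|$ reaches
   `deltaMin` = 2 bits (a small guard against alignment noise); below
   it, the discriminating features vote, and a tied vote returns
   `ambiguous`.

A global aligner can shift a mismatching residue away from a conserved
column when that is cheaper than the mismatch ("dodging"), so a single
alignment is not trustworthy evidence at a discriminating position.
Feature votes therefore read the residue at the matched column pair in
*both* model alignments and abstain on disagreement; element votes
require concordance between span occupancy (in the carrier's
alignment) and surplus insertions (against the model lacking the
element). Votes abstain rather than mislead; the score margin carries
the decision in the overwhelming majority of cases.

Covariance-model (SCFG) scoring of the Infernal kind is out of scope on
purpose: the discriminating features, not full homology-search
likelihoods, are the analytical object here.

## Assay quantification

**In-line probing.** Band tables (CSV: lane, molar concentration —
empty for the no-ligand lane —, modulated and constant band
intensities) are reduced to relative intensity changes
$r(c) - r(\varnothing)$ with $r = \text{modulated}/\text{constant}$.
`fitBindingCurve()` fits the Hill isotherm
$f(c) = f_{\max} c^{n} / (K_d^{n} + c^{n})$ by Levenberg-Marquardt
nonlinear least squares, with the response sign detected automatically
and the Hill coefficient free but bounded to [0.5, 3] (the bound guards
against overfitting sparse dose series; fixing n = 1 would assume more
than the data usually support). *Saturation* is called when the fitted
$K_d$ is at most max(conc)/5, the fitted values at the two highest
doses are within 10 percent of $f_{\max}$, and the plateau is
resolvable above the noise ($f_{\max} > 3\times$ rms residual — without
this, a flat noise-dominated series masquerades as an already-saturated
binder). When saturation is not reached, no apparent $K_d$ is reported
(`kd = NA`; the raw fitted parameter remains available as `fitKd` for
diagnostics) and the series is normalized to the value at the highest
usable concentration; normalized magnitudes are always capped at 1.
Non-monotone series (rank correlation with dose below 0.8) are flagged
and fitted anyway.

**Transcription termination.** Body-labelled transcription
([alpha-32P]-ATP) makes band intensity proportional to each product's
adenosine content, so intensities are divided by the products' A counts
before computing the terminated fraction
$\frac{t/A_t}{t/A_t + f/A_f}$. Whether published quantifications
correct for this is often unstated; the correction is applied by
default and can be disabled (`correctA = FALSE`).

**Acetylation assays.** A linear DTNB (Ellman's reagent) calibration is
fitted by ordinary least squares on at least three CoA standards;
released CoA is read off the line and clipped at zero with a warning.
Reporter fluorescence is normalized by OD600.

## The synthetic generator

`generatorProfile()` describes two motifs sharing a 61-column base
architecture — two hairpins connected by a pseudoknot, the 3' hairpin a
putative intrinsic terminator — and the differences planted between
them:

* three strict identity contrasts (frequency 1 in one motif, 0 in the
  other) at conserved unpaired columns, emulating binding-core changes;
* a 10-column hairpin inserted into the terminator loop of motif A
  only (complementary stem, sampled loop), emulating an extra element;
* conserved unpaired columns at 0.97 identity; stems sampled as
  canonical pair types (GC 0.45, CG 0.25, AU 0.15, UA 0.10, GU 0.05)
  so consensus pairs genuinely covary; low-conservation tails at 0.40
  majority and 0.85 present;
* gene-context labels correlated with motif membership: the variant
  motif is dominated by a transaminase-like domain (PRK07324) at
  probability 0.55 — matching the "over 50 percent" association that
  motivates this kind of analysis — the reference motif by a
  guanidine-exporter-like domain (COG2076) at 0.55, with
  acetyltransferase (GNAT) and MATE-transporter labels shared by both;
* three phyla (Actinobacteria, Bacteroidetes, Firmicutes at
  0.3/0.3/0.4) and environment labels with the variant motif
  gut-enriched 5:1 among known labels versus a balanced background —
  so the true enrichment odds ratio is 5;
* assay generators: a Hill isotherm with multiplicative lognormal band
  noise and a no-ligand lane over the standard 16-lane two-fold series
  from 20 mM down to ~0.61 uM; termination records with the A-count
  distortion applied; linear calibrations with additive noise.

Columns are sampled independently by default — the simplest model that
exercises every downstream contract. This deliberately omits
phylogenetic correlation between rows, alignment errors, indel
processes beyond presence gaps and the element span, and base
composition bias. Passing tests on this generator therefore demonstrate
correctness of the statistics and plumbing, not robustness to
phylogenetic redundancy or misalignment in real data; the `star` mode
(shared ancestor, per-sequence mutation rate) exists to probe the first
of these. Every generator is a pure function of its profile and seed,
restores the caller's RNG state, and reproduces bit-identical output on
reruns.

## Numerical choices and degenerate inputs

* Tier thresholds are compared with a 1e-9 epsilon; contrast grades use
  exact comparisons on empirical fractions.
* The column mapper and sequence aligner break ties deterministically
  (match state preferred, then gap-in-A before gap-in-B).
* MI uses pairwise deletion; pairs with fewer than 5 jointly present
  rows are excluded from the APC background and flagged.
* Empty alignments refuse consensus construction; single-row
  alignments put every residue column in the 97 tier (n = 1 is
  conserved by definition and flagged by no other mechanism).
* Zero-margin contingency tables return p = 1 with a `degenerate`
  flag; 0/0 odds ratios are `NaN` with the same flag.
* Constant binding responses warn and return a degenerate, unsaturated
  curve; all-zero series refuse normalization.
* The exact-test tie comparison uses a 1 + 1e-7 relative slack when
  summing tables "as extreme as" the observed one, the standard guard
  against floating-point ties in hypergeometric enumeration.

## Problem sizes used by the test suite

The packaged tests run the full analysis at 200 rows per motif and 20
generator replicates for feature recovery, 2000 rows for convergence
checks, 50 replicates for binding-curve recovery, and exhaustive
enumeration of all 2x2 tables with total count up to 40 for the exact
test. These sizes were chosen to hold empirical fractions within a few
tenths of a percent of their targets while keeping a full run in the
order of a minute; they are the package's own choices, and all of them
are plain arguments that scale up directly.

## Known limitations

* Column mapping is profile-based; two motifs with little shared
  conservation will still be mapped (the contract guarantees
  monotonicity and completeness, not homology).
* The classifier's feature vote abstains under alignment conflict, so
  sequences deep inside the ambiguity margin with conflicting
  alignments are labelled `ambiguous` rather than forced.
* Environment enrichment inherits whatever ascertainment bias the
  background set carries; the package treats the background as given.
* The in-line probing chain quantifies already-extracted band
  intensities; gel image processing is out of scope.
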