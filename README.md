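# MotifContrast

Comparative analysis of two homologous structured-RNA motif alignments
— the situation that arises when a candidate **riboswitch variant** is
discovered: a conserved RNA motif strikingly similar to a known
riboswitch class (shared hairpins, pseudoknot, intrinsic terminator)
but associated with different downstream genes, suggesting a different
ligand. The package is for computational RNA biologists who have two
curated Stockholm alignments and need to (i) model each motif's
consensus, (ii) locate the features that systematically discriminate
the motifs, (iii) quantify gene-context and environment associations,
(iv) classify new sequences into either motif, and (v) quantify the
standard wet-lab assays (in-line probing, transcription termination,
acetyl-transfer calibration) used to validate such candidates.

## What it computes

**Consensus models.** Per-column identity fractions among non-gap
residues with R2R-convention conservation tiers (97/90/75 % identity,
97/90/75/50 % present), plus covariation of every consensus pair by
mutual information with average product correction:

    MI(i,j) = sum_ab p_ab log2( p_ab / (p_a p_b) )     [bits]
    MI_APC(i,j) = MI(i,j) - mean_MI(i) * mean_MI(j) / mean_MI

computed over jointly non-gap rows; a pair is *covarying* when
MI_APC > 0.3 bits, ≥ 90 % of rows form canonical (WC/GU) pairs, and at
least two canonical pair types occur at ≥ 5 % frequency.

**Discriminating features.** After a profile-profile column mapping
(Gotoh affine DP; match = Σ f_A f_B + pairing-status bonus), matched
columns are scanned for identity contrasts (*strict*: ≥ 0.97 in one
motif and ≤ 0.03 in the other; *high*: 0.90/0.10) and unmatched column
runs (≥ 4) for structural elements present in one motif only
(occupancy-based, minimal hairpin = 6 residues).

**Context.** Gene-domain frequency tables for both motifs and exact
2×2 enrichment tests (full hypergeometric enumeration, sample odds
ratio a·d/(b·c)), e.g. gut versus non-gut environments against a
metagenome background.

**Classification.** Position-specific log-odds scores
log2((f(x)+α)/(0.25+α)) against both models; a sequence is labelled by
the higher score when the margin reaches 2 bits, otherwise the
discriminating features vote.

**Assays.** Relative band-intensity changes anchored at the no-ligand
lane; Hill-isotherm fits f(c) = f_max·c^n/(Kd^n + c^n) with an explicit
*no-saturation* rule (no apparent Kd is reported when the dose series
does not reach the plateau); terminated-transcript fractions with
adenosine-count correction for body-labelled products; linear DTNB
calibrations.

A seeded synthetic-data generator (`generatorProfile()`,
`generateMotifPair()`, `generateProbingTable()`, ...) emulates all of
this input structure — planted contrasts, an inserted hairpin,
correlated gene/environment metadata, noisy assay readouts — so every
analysis is testable end to end without external data.

## Worked example

```r
library(MotifContrast)

prof <- generatorProfile(seed = 42)           # two homologous motifs,
sim  <- generateMotifPair(prof, nA = 200,     # 3 planted contrasts +
                          nB = 200, seed = 42) # 1 inserted hairpin
modelA <- buildConsensus(sim$alnA)
modelB <- buildConsensus(sim$alnB)
modelA
#> ConsensusModel 'motifA': 71 columns from 200 sequences
#>   pairs: 21 (4 pseudoknot); 21 covarying
#>   identity tiers >=97/90/75: 12/3/0 columns

feats <- findDiscriminatingFeatures(sim$alnA, sim$alnB, modelA, modelB,
                                    mapColumns(modelA, modelB))
subset(feats, grade == "strict")
#>                kind motif colA colB spanStart spanEnd   nt freqA freqB contrast  grade
#> 1  element_presence     A   NA   NA        46      55 <NA>     1     0        1 strict
#> 2 identity_contrast  both   26   26        NA      NA    C     1     0        1 strict
#> 3 identity_contrast  both   27   27        NA      NA    A     1     0        1 strict
#> 4 identity_contrast  both   34   34        NA      NA    C     0     1        1 strict

query <- gsub("-", "", gappedSeqs(sim$alnA)[[1]])
classifySequence(modelA, modelB, feats, query)
#> ClassificationResult: label = A (scoreA = 61.88, scoreB = 22.56, delta = 39.32 bits)
#>   feature votes: A A A A

environmentEnrichment(sim$alnA, c(gut = 50, non_gut = 50))
#> ContingencyResult (fisher)
#>            gut non_gut
#> motif      161      27
#> background  50      50
#>   odds ratio: 5.963  two-sided p: 2.245e-10
```

The four strict features are exactly the planted ones: three nucleotide
identity contrasts at mapped columns 26, 27 and 34 (e.g. column 26 is
always C in motif A and never C in motif B) and the 10-column hairpin
(columns 46–55 of motif A) that motif B lacks entirely. The query — a
motif-A member — scores 39.3 bits higher against model A, and all four
feature votes agree. The variant motif's sequences are gut-enriched
roughly six-fold against a balanced background (the generator plants a
5:1 ratio).

A command-line wrapper over the same functions is installed at
`inst/scripts/motif-contrast.R`
(`Rscript motif-contrast.R simulate seed=7 outdir=out`, then
`compare`, `context`, `enrich`, `classify`, `probe-quant`,
`term-quant`, `calibrate`); see `?runPipeline`.

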