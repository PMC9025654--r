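---
title: "Motif-guided targeted databases for immunopeptidome searches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-guided targeted databases for immunopeptidome searches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introspectr)
```

## The problem

HLA class I ligands are produced by proteasomal cleavage, not by a
sequence-specific enzyme, so a database search for immunopeptidome mass
spectrometry must consider *every* 9--11-mer substring of the proteome --
on the order of $10^8$ candidate peptides.  Against a search space that
large, true peptides compete with an enormous number of irrelevant
candidates, q-values inflate, and sensitivity at a fixed FDR drops sharply.

Most of that space is, however, irrelevant for any one sample: the ligands
presented by a cell's particular HLA alleles share strong sequence motifs,
with anchor residues typically at P2 and the C-terminal position.
`introspectr` exploits this by a two-round strategy:

1. a first, conventional unspecific-digestion search yields a set of
   high-confidence peptides (1% peptide-level FDR);
2. these peptides are deconvoluted into motif clusters and per-motif
   position-specific scoring matrices (PSSMs) are trained;
3. the full k-mer space is scored and only peptides with motif score above
   a threshold (default 0.3) are kept;
4. every first-round peptide is added to this targeted database, which is
   then searched again.  Because the final search runs once against one
   database, its FDR is a single *global* FDR -- nothing has to be stitched
   together across rounds.

The package learns everything from the first-round hits themselves; no
external HLA binding data or allele assignment is needed, so well-studied
and poorly-studied alleles are treated identically.

## The model

### Motif deconvolution

`cluster_peptides()` partitions peptides into $K$ motif clusters over a
length-9 core alignment, for $K$ in a configured range (default 1--6).
Peptides of length 9--11 are aligned to the core by deleting up to 2
interior residues; the first and last residues are never deleted, because
they carry the anchor positions.  The sampler is simulated annealing over
the state (cluster, alignment) of every peptide: one sweep visits the
peptides in seeded-random order, removes each from its cluster's counts,
scores every candidate (cluster, alignment) by the peptide's leave-one-out
log2-odds fit

$$ s(p \mid c) \;=\; \sum_{i=1}^{9} \log_2 \frac{\tilde f_{c,i,a_i}}{B_{a_i}},
\qquad \tilde f = \frac{F + \omega B}{1 + \omega}, $$

and samples one with probability $\propto \exp(s/T)$.  The temperature
ladder is geometric from 1.5 to 0.05 over 20 steps with 10 sweeps per step
(configurable), followed by zero-temperature greedy sweeps run to a fixed
point.  Each $K$ is attempted from 5 seeded initial conditions and the
best run by the objective below is kept.

After the final sweep, peptides whose best fit falls below the trash
threshold are discarded to a trash cluster and excluded from the cluster
frequency matrices.  The published parameterization states the threshold as
"2" without units; we interpret it on the **total** log2-odds scale (bits
summed over the 9 core positions), where typical motif peptides score 4--8
bits and background peptides near or below zero.  The per-position-average
reading (`trash_score_scale = "per_position"`) is also available, but at
2 bits *per position* it discards essentially every real peptide --
two 0.7-mass anchors contribute only about 0.6 bits per position on
average -- so it is not the default.

### Model selection by KLD

The number of clusters is chosen by maximizing

$$ \mathrm{KLD}(K) \;=\; \sum_{c=1}^{K} \frac{n_c}{N}\, w_c\,
   \mathrm{KLD}_c \;-\; \lambda \sum_{c < c'} \max\{0, \rho(F_c, F_{c'})\}, $$

where $\mathrm{KLD}_c$ is the information content of cluster $c$'s smoothed
core frequencies against the background, $w_c = \min(1, n_c / (\sigma L))$
down-weights clusters smaller than $\sigma$ times the motif length
(default $\sigma = 5$), and $\rho$ is the Pearson correlation between
vectorized cluster frequency matrices, clipped at zero so that only
positive similarity is penalized ($\lambda = 0.8$).

Two numerical choices matter here.  First, the plug-in estimate of
$\mathrm{KLD}_c$ is biased upward by roughly $19L / (2 n_c \ln 2)$ bits
(the Miller--Madow entropy bias with 20 categories): uncorrected, small
clusters look spuriously sharp and the selected $K$ drifts upward.  We
subtract this bias and clamp at zero.  Second, the sampler's pseudocount
weight defaults to $\omega = 0.5$, stronger than the $\omega = 0.1$ used
for final PSSM training.  The sampler scores single peptides against
small, shifting clusters; with weak smoothing a single anchor mismatch
costs so many bits that ordinary motif peptides fall below the trash
threshold, and overfit fragments of one motif win the model selection.
Both values were fixed from this qualitative behaviour on synthetic data
(a single planted motif must select $K = 1$, two disjoint motifs $K = 2$)
and are configurable.

The greedy polish maximizes each peptide's own leave-one-out fit; under
the renormalized pseudocount scheme this is not *exactly* coordinate
ascent on the summed objective, so a sweep can in rare cases lower the
total slightly.  The polish therefore runs to a fixed point (a sweep that
moves nothing), which is the property the tests assert.

### PSSM training and scoring

For each cluster, `train_pssm()` smooths the positional frequencies $F$
with background pseudocounts and scores a peptide as the *sum* of its
per-position entries (no length normalization).  The printed form of the
matrix entry, `log(F + omega * B)`, yields only negative scores -- a sum
of log-frequencies -- which cannot produce a positive filter threshold;
the default is therefore the log-odds form
$P_{ai} = \log_2(\tilde f_{ai} / B_a)$, under which background-distributed
peptides score near zero and the 0.3 threshold is meaningful.  The literal
form is retained as `scoring_form = "as_printed"` for comparison.

Because ligand motifs are length-specific, `motif_model()` trains one PSSM
per (cluster, length) with at least `min_train = 20` peptides of that
exact length, plus a 9-mer core model per cluster.  At prediction time a
length with its own PSSM uses it; a length seen among the hits but with
too few peptides falls back to the core model maximized over legal
deletion placements (flagged `core_aligned`); a length absent from the
hits carries no motif evidence and is left unscored -- its k-mers never
enter the database through the motif route.

The pseudocount weight is described in the original method only as drawn
from a Dirichlet distribution without parameters; we use a fixed
$\omega = 0.1$ for training (configurable), which keeps every entry finite
without washing out anchor information.

### Database composition

`build_targeted_database()` enumerates the unique 9--11-mer space
(`enumerate_kmers()`, ambiguity-code windows skipped), keeps k-mers with
best motif score strictly above the threshold, and unions them with
**all** first-round peptides, whether or not they pass the filter or even
occur in the proteome (a neoepitope FASTA entry, for instance, does not).
This superset rule is what preserves the global FDR of the second round,
and it is property-tested across randomized builds.  Contaminant-protein
k-mers can be added unfiltered under their own provenance tag, so that
post-search contaminant elimination remains possible; this is off by
default.  The output FASTA is written in lexicographic byte order with
provenance and best score in the headers, so identical builds are
byte-identical.

## What the synthetic generators emulate

`motif_spec()` + `sample_motif_peptides()` draw peptides from a positional
model with anchor residues at configurable positions (default P2 and P9,
mass 0.7, remainder spread proportionally to the background), mixed with
background peptides at a configurable noise fraction.
`plant_proteome()` embeds peptides verbatim into background-sampled host
proteins (default length 100--400) plus filler proteins.  These emulate
the anchor structure of real HLA ligand sets and give exact ground truth
for recovery tests.

They do *not* emulate several features of real data: non-uniform peptide
abundance, chemically similar residues sharing anchor roles (real anchors
are residue *classes*; the generator plants a single residue), correlated
positions, modified peptides, or real spectral noise.
`simulate_two_round_gain()` likewise reduces the search engine to score
draws: a spectrum's true match scores $N(\mu_t, \sigma)$, a spectrum whose
peptide is missing from the database gets the maximum of
$k = \lceil c\,|db| \rceil$ random draws, and decoys are a same-size
reversed set scored the same way.  This is the simplest competition model
in which shrinking the database raises identifications at fixed FDR; it
says nothing about absolute sensitivities on real spectra.  Passing tests
therefore demonstrate the *mechanism* and the pipeline's internal
guarantees, not performance on real mass spectrometry data.

## Problem sizes used by the tests

The test-suite and the acceptance script run, by design, at desk scale:
window-counting identities on 20 random proteomes of 100 proteins
(lengths 20--500); two-motif recovery over 20 replicates of 100 + 100
peptides with 5% noise; 100 randomized small builds for the superset rule;
one planted proteome of 200 motif 9-mers in 700 proteins (about
$5 \times 10^5$ unique k-mers); and the search simulation at database
sizes $10^4$--$10^6$ with 2000 spectra.  On these conditions the targeted
database is about 2% of the full space, contains 100% of the planted and
first-round peptides, and identifies many times more spectra at 1% FDR
than the full-space search.

## Known limitations

* The sampler re-implements the published clustering procedure from its
  printed parameter list; unprinted internals (sequence weighting,
  BLOSUM-informed pseudocounts, exact trash-score scale) are fixed by the
  documented choices above, so cluster-level results need not match the
  original tool peptide-for-peptide.
* With fewer than a few hundred first-round hits the per-length training
  sets become small; the build warns below `min_total_hits = 500`.
* Scores are filtered at a hard threshold; no probabilistic weighting of
  candidates is attempted.
* Insertions in the core alignment are not supported
  (`max_insertions = 0`).
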