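---
title: "Germline-conditional nanobody library design with nanolibkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Germline-conditional nanobody library design with nanolibkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanolibkit)
```

## The problem

Nanobodies (VHH domains) are single-domain antibody fragments of roughly
110–130 residues. Their antigen-binding surface is carried by three
hypervariable loops (CDR1–CDR3) mounted on a conserved scaffold (FR1–FR4)
whose sequence derives from a germline V gene. Synthetic nanobody libraries
are traditionally built by grafting combinatorially varied CDRs onto a fixed
framework; the quality of such a library depends on how faithfully the CDR
variation reflects the germline-specific statistics of real repertoires, and
on keeping chemical liability motifs out of the scaffold.

`nanolibkit` implements that workflow end to end at desk scale:

1. **Curation** — align a repertoire to germline V-gene references, keep
   sequences more than 85% consistent with their best-matching germline,
   deduplicate, length-filter, and split 80/20 into train and test sets.
2. **Numbering** — transfer IMGT numbering from the assigned reference by
   anchor alignment, delimit FR/CDR regions, and check the conserved
   C23/C104 cysteine pair.
3. **Generation** — train a small decoder-only autoregressive amino-acid
   language model with LoRA adapters, conditioned on a germline tag, and
   sample new sequences per germline; a purely statistical PSSM sampler is
   available as a baseline.
4. **Assessment** — scan generated sequences for PTM liability motifs and
   score germline-conditioning fidelity by best-identity assignment.
5. **Library synthesis** — compute length-stratified positional amino-acid
   frequency matrices per CDR and graft independently sampled loops into a
   fixed, highly humanized donor framework.

A synthetic-repertoire simulator (`simulate_repertoire()`) stands in for
experimental data, so every stage is exercisable and testable offline.

## Curation model

"Consistency" with a germline is percent identity computed over the
alignment columns in which the reference carries a residue: a VHH aligned to
a V gene accumulates a long reference-gap region at CDR3, and counting those
columns would penalize long loops rather than framework divergence.
Reference residues deleted in the query count as mismatches. Alignments are
end-to-end Needleman–Wunsch under BLOSUM62 with gap open 11 / extend 1 —
standard protein-alignment parameters, chosen for determinism rather than
tuned. The retention rule is strict (`identity > 0.85`), applied to the
best-matching reference.

The length filter defaults to 90–160 aa: generous bounds around the
110–130 aa bulk of VHH domains, intended only to drop fragments and
concatemers; it is configurable in `curate_dataset()`.

## Numbering by anchor transfer

The pipeline only ever numbers sequences that are at least 85% identical to
a known reference (50% is the hard floor), so full profile-HMM numbering is
unnecessary: a query inherits IMGT positions from its reference through the
global alignment. Insertions receive insertion codes on the preceding
position; the tail beyond the reference's last residue (IMGT 104) is split
into CDR3 — numbered 105–117 by the IMGT junction convention, with
111.x/112.x insertion codes for loops longer than 13 — and FR4, numbered
from 118 and right-anchored on the last `WGQG` J-segment motif in the tail.
When no `WGQG` is present, the first 13 tail residues are treated as CDR3
and the rest as FR4. Region delimitation uses the fixed IMGT boundaries
(CDR1 27–38, CDR2 56–65, CDR3 105–117), exposed as `IMGT_BOUNDS`.

The bundled germline references are *synthetic stand-ins*: V-region
backbones of the two bundled donor frameworks (through IMGT 104) with
hand-assigned IMGT maps following the standard conventions (25-residue FR1
with the gap at position 10; 38-residue FR3 with the gap at 73; loop gaps
filled from both ends). They emulate the alpaca alleles IGHV3-3\*01 and
IGHV3S53\*01 and already differ at 15% of framework positions, which makes
germline assignment identifiable; they are not copies of IMGT database
records.

## The LoRA generator

The generator is a LLaMA-style decoder: pre-norm residual blocks with
multi-head causal self-attention (rotary position embeddings on queries and
keys) and a SwiGLU feed-forward, a weight-tied output head, and RMS
normalization without learned gains. Defaults are deliberately small —
`d_model = 128`, 4 layers, 4 heads, `d_ff = 256` — because the properties
the package establishes (the low-rank update algebra, the freeze contract,
and germline conditioning) do not depend on parameter count.

Every base matrix is frozen at initialization. Each of the seven projections
per block (`wq, wk, wv, wo, wgate, wup, wdown`) carries a low-rank adapter:
the effective weight is `W0 + A B` with `A` of shape `d x r` and `B` of
shape `r x k`. `B` starts at zero, so the adapted model is exactly
function-identical to the base before training — a property the tests assert
to floating-point identity. The default rank is `r = 8` with scaling 1.0
(no `alpha/r` rescaling), giving a trainable fraction just under 10% of
parameters for the default architecture; `trainable_fraction()` reports the
closed-form count. Training minimizes next-token cross-entropy with Adam
(default 4 epochs, learning rate 2.5e-3, batches of 16 equal-length
sequences): on the simulated repertoires used throughout, the loss reaches
its plateau — within a few hundredths of a nat of the simulator's entropy
floor of roughly 0.5 nats/token — inside that budget, and longer schedules
did not change assignment accuracy. The gradient path through attention,
RoPE, SwiGLU and RMS-norm is hand-derived and verified against numerical
differentiation in the test suite.

Conditioning is a single categorical tag token prefixed to each sequence
(`[tag][begin]residues[end]`). A natural-language instruction would add
phrasing, not signal, so the tag is the whole instruction. Sampling is
temperature-1 ancestral sampling with an end token, duplicates dropped;
samples that fail alphabet validation or fall below the 0.5 numbering
identity floor are resampled (sampling uses a compiled cached-attention
kernel; a batch of 500 sequences decodes in about half a minute on one
CPU).

## Liability scanning

The default motif table encodes standard antibody developability practice —
high risk: N-glycosylation sequons `N[^P][ST]`, deamidation `NG/NS/NT`,
isomerization `DG/DS/DT`, acid hydrolysis `DP`, and any cysteine outside
the conserved IMGT 23/104 pair; medium risk: methionine/tryptophan
oxidation and the weaker deamidation contexts `NN/NA`. The table is a TSV
data file (`load_motif_table()`), not code, so alternative counting
conventions are a file edit away. Overlapping matches are all reported
(`NGS` is both a deamidation site and a sequon). Without a region
annotation the unpaired-cysteine rule is skipped, because "unpaired" is
defined by IMGT position.

## Library synthesis

`compute_pfm()` gives raw per-column frequencies (no smoothing — these are
the quantities a sequence logo displays; the PSSM *sampler* uses a 0.01
pseudo-count because it must never assign probability zero). CDR3
statistics are length-stratified; the default strata follow the lengths
with the most data per germline (15–19 for IGHV3-3\*01, 12–16 for
IGHV3S53\*01), weighted by empirical counts. Columns are sampled
independently within each region — per-site frequencies are exactly the
statistic the library construction uses; pairwise couplings are an explicit
non-goal. Because the donor framework contributes FR1–FR4 unchanged, every
library member retains C23/C104 and remains annotatable by construction.

## The simulator

`simulate_repertoire()` emulates a germline-restricted repertoire: the
donor framework mutated per-residue at rate 0.03 in framework columns
(typical somatic divergence for curated, germline-consistent sets) and 0.15
in CDR1/CDR2 (their much higher variability), with CDR3 resampled wholesale
from a germline-specific seed PFM (55% consensus mass per column, the rest
uniform) at a length drawn from the paper strata. Substitutions are uniform
over the 19 alternatives — the simplest null for recovery tests.
`anchor_protection` keeps C23, C104 and the FR4 `WGQG` anchor fixed; the
CDR3 alphabet excludes C and W so the cysteine count and the FR4 anchor
stay unambiguous, which is what makes exact CDR-string recovery a fair
test. What the simulator does *not* reproduce: substitution-matrix bias,
hypermutation hotspots, indels within frameworks, lineage structure, and
cross-position dependence within CDRs. Tests passing on simdata therefore
demonstrate pipeline correctness in the curated, germline-consistent
regime, not robustness to raw repertoire data.

## Numerical and design choices

- Equal-scoring alignment ties resolve by the fixed traceback order of the
  dynamic program (substitutions preferred over gaps); identity values are
  unaffected.
- The 85% threshold is applied to the best-matching germline, since the
  curation question is "is this sequence germline-consistent at all".
- Batch germline assignment computes identity as matched columns divided by
  reference width, which is algebraically identical to the per-alignment
  definition but avoids materializing aligned strings.
- RMS normalization uses eps 1e-6; training aborts on non-finite loss.
- The model checkpoint is a single RDS file; all other artifacts are plain
  text (FASTA/TSV/JSON).
- Problem sizes used by the shipped experiments: 500 simulated sequences
  per germline for training, 1,000 generated sequences per conditioning
  tag for accuracy, 20,000 samples for the PFM recovery check. These are
  the sizes at which the sampling error of each measured quantity is
  comfortably below the margin being tested.

## Worked example

```{r example, eval = FALSE}
library(nanolibkit)

# simulate two germline-restricted repertoires
sims <- lapply(nano_germlines(), function(g) {
  simulate_repertoire(repertoire_config(g, 500, seed = 1))
})
recs <- do.call(rbind, lapply(sims, `[[`, "records"))

# curate against the bundled references
cur <- curate_dataset(recs, nano_references(), seed = 2)

# train the germline-conditional generator and sample
model <- attach_lora(lora_spec(nano_germlines()), seed = 3)
model <- train_generator(model, cur, seed = 4)
gen <- generate_sequences(model, "IGHV3S53*01", 1000, seed = 5)
germline_accuracy(gen, "IGHV3S53*01", nano_references())

# annotate, scan, and build a grafted library
anns <- annotate_repertoire(gen, nano_references())
design <- design_from_annotations(anns, "IGHV3S53*01")
lib <- synthesize_library(design, 10000, seed = 6)
```

The full pipeline, with artifacts and a manifest, is `run_pipeline()`; a
bundled demo configuration (`demo_pipeline_config()`) completes in a
minute or two on one CPU.

## Known limitations

- Anchor-transfer numbering is only valid near a known reference; it is not
  a general-purpose numberer and refuses queries below 50% identity.
- Two bundled germlines; adding more requires a reference sequence with an
  IMGT map and a donor framework.
- The generator is desk-scale: it learns the conditional statistics of the
  repertoires it is trained on and is not a pretrained protein language
  model.
- Liability scanning is sequence-level; it does not weight sites by
  structural exposure or predict modification rates.
- Humanization scoring and structure-based evaluation (pLDDT, TM-score,
  RMSD, disulfide geometry) are out of scope; the cysteine check is the
  sequence-level surrogate for the conserved disulfide.
```
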