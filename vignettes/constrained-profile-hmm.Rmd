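---
title: "Segment-constrained profile HMMs for light-chain amyloid template scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-constrained profile HMMs for light-chain amyloid template scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilHMM)
```

## The problem

In AL (light-chain) amyloidosis, clonal antibody light chains (LCs) misfold
into amyloid fibrils that deposit in organs. Only a handful of LC fibril
structures have been solved, and they do not represent the diversity of
amyloidogenic LC sequences. When a new amyloid-prone LC sequence is found, two
questions matter: *which solved fibril structure is it most similar to*, and
*is that similarity high enough that homology modeling of its fibril state is
trustworthy*? fibrilHMM answers both with one hidden Markov model (HMM) per
structural template, scoring sequences against every template, aligning them
to the best one, and — when the decision rule passes — preparing a
pruned-backbone side-chain modeling job for an external force field.

Because fibril backbones cannot be remodeled reliably, the whole design is
conservative: the model only claims a structure when the answer is nearly
self-evident from sequence similarity, and the alignment machinery is
constrained so that misalignments in structure-bearing regions are
essentially impossible.

## The model

Each template is one chain of one fibril layer from a solved structure. Its
structurally resolved residues, in order, form the *consensus*; jumps in
author residue numbering mark *missing segments* (regions invisible in the
map); and the complementarity-determining regions (*CDRs*) are declared
per-template in an annotation config, because CDR numbering conventions
differ and the choice should stay in the operator's hands.

The HMM topology mirrors the biology of LC variable domains — conserved
framework regions alternating with hypervariable CDRs:

* one MATCH state per consensus position; **within constant regions the match
  states chain directly**, with no insert or delete neighbours — indels in
  frameworks are rare, and forbidding them drastically reduces misalignment;
* between consecutive resolved segments, a single self-looping skip state
  absorbs the residues spanning the unresolved segment (geometric length,
  extension 0.9 / termination 0.1);
* within each CDR, standard profile wiring: gap open 0.1 split evenly between
  match→delete and match→insert, extensions 0.9;
* uniform-emission flank states at both termini absorb unaligned residues, so
  gaps are tolerated only at the sequence ends and inside CDRs.

A deliberate and unusual choice: the "deletion" states *emit* residues
(uniformly, 0.05 per amino acid) rather than being silent. A deletion here
does not mean the query lacks residues — it means the query has residues with
no template coordinates (an unresolved segment, or a CDR stretch that cannot
be matched). Emitting skip states absorb exactly those residues, and because
they carry emission parameters they can be trained like any other state.

Untrained ("dummy") emissions put 0.8 on the template residue of each match
state and spread 0.2 over the other 19 amino acids.

### Local entry and exit

Two topology parameters are not dictated by the parameterization above but
are required for the semantics the alignment contract demands. With a strict
match chain, every path would have to visit all consensus positions, so a
query whose N- or C-terminal template region is absent or unalignable would
have zero probability. We therefore allow:

* `entry_open` (default 0.1): probability mass of entering the match chain
  after position 1, spread uniformly over positions 2..L;
* `exit_open` (default 0.01): each interior match state's probability of
  exiting to the C-flank/END early.

Interior match states thus pass all non-terminal mass, `1 - exit_open`, to
their unique chain successor. Both parameters are configurable in
`hmm_build_params()`; the defaults are mild enough that a full-length match
always dominates when one exists (the consensus query decodes to the pure
match path with zero flanks), while a query with 20 unalignable N-terminal
residues decodes to flank absorption plus entry at position 21 — gapless
coverage 0.8 on a 100-position template.

## Scoring and calibration

The raw score of a sequence is the log-ratio between its backward probability
under the template HMM and the average backward probability of 100 random
shuffles of it. Shuffling preserves length and composition, so the null
controls for both. The shuffle average is taken in probability space
(log-sum-exp minus `log n`), reading the "average probability" literally; a
log-space average is available via `raw_score(average = "log")`. The choice
matters for the score's absolute location — the probability-space average
sits systematically above the geometric mean (Jensen's inequality), so raw
scores of background sequences center slightly below zero under the default
and exactly at zero under `"log"` — but it does not affect any downstream
decision, because calibration is monotone.

Calibration maps raw scores to empirical quantiles of the training corpus:
sorted reference scores get quantiles 0..1, queries are interpolated linearly
and clamped, so calibrated scores live in [0, 1] and 0.5 means "median of the
amyloid training corpus". Degenerate sequences (zero likelihood, `-Inf`
sentinel) are excluded from fitting and calibrate to 0 with a flag.

## Training schedule

Each template model starts from the dummy parameterization and is refined on
an amyloid-LC corpus (full-length sequences only, ≥ 211 residues) by
Baum-Welch with *inertia*: every update is
`new = 0.9 · old + 0.1 · expected-count estimate`, stopping when the corpus
log-likelihood improves by less than 50. Inertia keeps the constrained
topology's strong priors from being washed out by a small corpus; the convex
update provably cannot decrease the likelihood (the EM surrogate is concave
in the parameters), which the suite checks. A floor of 1e-10 on count
estimates prevents finite corpora from creating permanent zeros; transitions
with structural probability zero stay zero, so training never relaxes the
topology.

The schedule is iterative self-selection: score the whole corpus, retrain on
the top 30%, rescore, retrain on the top 20%, rescore, retrain on the top
10%, then score once more and fit the quantile calibrator on those final
scores. Top-k counts use `ceiling(f · N)`; boundary ties keep input order
(recorded in the training log, so runs are reproducible bit for bit from the
seed). Selection uses raw scores — the calibrator is fitted exactly once, at
the end.

## Template selection and the modelability rule

A query is scored against every registered template; the best template is
the calibrated-score argmax (ties: lexicographic template id). The sequence
is declared reliably modelable only when

* the best calibrated score **exceeds 0.5** (strict: "above the median"), and
* **at least 80%** (non-strict) of the template consensus is covered by
  gapless match alignment.

The coverage denominator is the template consensus length — the quantity
homology modeling actually needs; `coverage_denominator = "sequence"`
switches to the query-length convention. CDR indels do not break the
constant, structure-bearing segments, so they do not reduce coverage beyond
the positions they actually delete.

## Structure building

For a modelable query, the template backbone is pruned to the aligned
consensus positions — symmetrically on every chain of the fibril stack — and
a side-chain job is emitted for an external force field's model-building
command: the pruned PDB plus a mutation list
(`<wt><chain><number><mutant>;` tokens) covering every aligned position where
the query differs from the template, applied to all chains. Retained
ATOM records are copied verbatim from the input file, so backbone coordinates
are unchanged byte for byte; running the job on the template's own sequence
at full coverage is a no-op (empty mutation list). Execution of the force
field itself is out of scope; the package emits its inputs.

## The synthetic study system

`generate_fixture()` builds the system every test runs on: a random
consensus with declared CDRs and missing segments, a minimal multi-chain
backbone PDB with matching author numbering, and a corpus *sampled from the
template HMM*: match positions emit the consensus residue or, with the
mutation rate, another one; CDR indel events insert residues or replace
match emissions by skip emissions; missing segments always emit their
unresolved residues; random flanks attach with probability 0.3 per terminus.
Ground-truth alignments are recorded, and at zero noise they coincide with
Viterbi decoding.

Defaults emulate the study conditions used throughout: a 60-position
template with one 12-position CDR, 200 sequences at 10% per-position
mutation and 10% per-CDR indel rate for the training experiments; smaller
templates for unit fixtures. What the generator does *not* emulate:
germline structure (all sequences descend from one template, not a mixture
of V-gene families), realistic amino-acid composition, correlated
mutations, and sequencing artifacts. Passing tests therefore demonstrate
the machinery — constrained alignment, recovery of the generating
emissions, calibration behavior, decision boundaries — not clinical
performance on patient-derived sequences, which depends on curated corpora
and solved fibril structures outside the package.

## Numerical choices

* All inference runs in natural-log space; `-Inf` is the zero-probability
  sentinel and propagates without arithmetic exceptions. Forward and
  backward agree within 1e-6 on every fixture (typically 1e-13), and
  likelihoods stay finite for 300-residue sequences against 250-position
  templates.
* Viterbi ties break deterministically: MATCH over DELETE_EMIT over INSERT
  over FLANK predecessors, then the lower state index — favouring template
  coverage.
* The Baum-Welch stop threshold is interpreted as absolute change in *total
  corpus* log-likelihood (the convention of the training library the
  schedule's defaults come from); `max_iterations` (default 500) bounds
  pathological cases.
* Problem sizes in the test and acceptance runs — 50 enumeration oracles up
  to 6 emitting states × 6 residues, 20 random topologies, one 200-sequence
  training experiment — were chosen as the smallest sizes at which each
  property is meaningfully exercised.

## Known limitations

* With only a handful of solved LC fibril structures, calibrated scores
  measure similarity to *known* templates; a low score vector flags novelty,
  not non-amyloidogenicity.
* The emitting-deletion convention means a query genuinely lacking residues
  across an unresolved segment still pays one emission there; segment-length
  polymorphisms are not modeled.
* CDR annotation is the operator's responsibility; the package deliberately
  refuses to infer numbering schemes.
* Entry/exit transitions allow partial-template alignment but are
  heuristically parameterized; extremely short queries can align locally
  with deceptively high calibrated scores — which the coverage rule exists
  to catch.

## A worked example

```{r, eval = FALSE}
fx <- generate_fixture(fixture_spec(template_length = 60L,
                                    cdr_intervals = list(c(25L, 36L)),
                                    corpus_size = 200L, rng_seed = 7L))
initial <- build_initial_hmm(fx$template)
fit <- iterative_retrain(initial, fx$corpus, training_config(rng_seed = 3L))
rep <- calibrated_score(fit$calibrator,
                        raw_score(fit$model, fx$template$consensus, 100L, 11L))
rep$calibrated_score   # the clean consensus ranks at the top of the corpus

registry <- list(template_model(fit$model, fit$calibrator, fx$template))
select_template(registry, fx$corpus[[1L]], "patient-LC")
```
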