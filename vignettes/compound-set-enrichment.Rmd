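---
title: "Compound-set enrichment and cluster analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound-set enrichment and cluster analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Early-phase screening produces a *set* of compounds — hits from a
phenotypic assay, actives from a library — whose shared biology is what
the experiment was really after. compset interprets such a set
collectively: which bioassays' hits it is enriched in (pointing at
targets and mode of action), which target families and disease classes
its known interactions concentrate in, and whether structurally similar
subgroups carry distinct annotation profiles.

## Compound standardization

Public databases register the same molecule many times over — salts,
protonation states, isotope labels. All analyses here operate on a
*merge key*: the 27-character standard InChIKey of the structure after
normalization (isotope mass labels stripped, charges neutralized where a
proton can be added or removed without violating valence, explicit
hydrogens removed). Lovastatin-style redundancy — dozens of database
entries, one molecule — collapses to a single registry record whose
`members` column preserves the original ids.

Two choices deserve comment:

* **Stereochemistry is kept.** Enantiomers receive different merge keys
  by default, because their biology can differ. `merge_registry(...,
  skeleton = TRUE)` merges on the 14-character connectivity block
  instead when a stereo-insensitive registry is wanted.
* **Normalization before keying.** Standard InChIKeys alone distinguish
  protonation states, so the intended collapse of charged forms is
  realized by neutralizing *before* key generation rather than by
  post-hoc key surgery.

Parsing, canonicalization, neutralization, descriptors and FP2
fingerprints go through Open Babel (via ChemmineR/ChemmineOB). One
implementation note: the in-memory conversion route drops tetrahedral
stereo when writing InChI, so merge keys are generated through the
`obabel` executable in a single batched call per registry.

## Properties and drug-likeness

`compute_properties()` adds MW (g/mol), logP (Open Babel's
atom-contribution model), TPSA (Å²), H-bond donor/acceptor counts,
Lipinski violations, and QED. logP is model-dependent; tests therefore
pin determinism and cross-toolkit agreement on fixtures, never absolute
logP values.

* **Lipinski**: violations counted among {MW > 500, logP > 5, HBD > 5,
  HBA > 10}; boundary values are compliant; a compound *passes* with at
  most one violation (the rule's customary reading).
* **QED** is the weighted geometric mean of eight desirability functions
  (Bickerton et al. 2012, *Nature Chemistry* 4:90–98); the published ADS
  parameters are transcribed verbatim and the machinery is exposed as
  `qed_from_descriptors()`, which reproduces the reference
  implementation to well under 1e-6 when fed the same descriptor
  values. Weights default to unit (unweighted geometric mean), with the
  published "mean" and "max" presets available. The bundled
  structural-alert catalogue is a reduced curated set (16 common
  reactive/undesirable motifs) rather than the full 94-pattern
  supplement; `qed_score(..., alerts_file=)` accepts any catalogue, and
  descriptor injection allows exact reproduction of any toolkit's QED.

Fingerprints are Open Babel FP2: linear paths up to length 7 hashed into
1024 bits; narrower widths (down to 64) are produced by OR-folding,
which preserves set bits at the cost of collisions.

## Hit calling

`assign_hits()` applies a three-criterion policy per assay:

1. If active/inactive **flags** exist, they define the hit set.
2. Otherwise, compounds with activity **Z-score ≥ 2** are hits. Values
   are oriented so larger means more active (a mandatory per-assay
   `direction` column — potency readouts are never guessed from titles),
   and standardized with the *sample* standard deviation (n − 1); an
   all-equal assay has no defined Z-score and contributes no Z-hits.
3. The **top 1%** (k = max(1, ⌊0.01·n⌋) compounds, plus every compound
   tied with the k-th value — ties are measurements, not rank labels)
   also counts as hits; the final set is the **union** of 2 and 3.

Z-scores are computed per assay over its tested compounds, not against a
global background: assay readouts are not on a shared scale. A `min_n`
guard (default 20) withholds the statistical criteria from tiny
unflagged assays, where a Z-score is mostly noise; flagged assays are
exempt.

## Enrichment statistics (CSEA)

For a query set $Q$ and an assay with hit set $H$ over its tested
compounds, the hit-enriched-assay score is the log-likelihood ratio

$$\mathrm{ES}_{\mathrm{HEA}} = \log_2 \frac{|Q \cap H| \,/\, |Q^{C} \cap H|}{|Q| \,/\, |Q^{C}|}$$

in bits; 0 means the query's share of hits matches its share of the
assay. For target/disease trees the score is the log2 odds ratio on
*interaction pairs* (compound–entity edges aggregated over each term and
its descendants):

$$\mathrm{ES}_{\mathrm{TET/DET}} = \log_2 \frac{|Q \otimes H| \,/\, |Q^{C} \otimes H|}{|Q \otimes H^{C}| \,/\, |Q^{C} \otimes H^{C}|}$$

Choices and caveats:

* **Per-assay universe.** $Q$ and $Q^C$ are restricted to compounds
  tested in the assay at hand — untested compounds carry no evidence.
  A `universe = "global"` mode exists for the alternative reading.
* **Zero cells.** A Haldane–Anscombe 0.5 is added (to both hit counts
  for the LLR; to all four cells for the odds ratio) only when a zero is
  present, keeping every score finite.
* **Significance** is the one-sided Fisher exact (hypergeometric upper
  tail) test in the enrichment direction — the standard exact choice for
  a 2×2 enrichment — with Benjamini–Hochberg FDR across all units of one
  run (all assays, or all terms of one tree).
* **Ranking** is by ES descending, ties broken by p then unit id, so
  reports are fully deterministic. Results at ES ≥ 5 are flagged as the
  conventional reporting cut.
* **Interpretation.** Tree enrichment assumes compounds outside $Q$ do
  not interact beyond their recorded edges; sparse annotation inflates
  scores. Pair-level p-values also treat pairs sharing a compound as
  exchangeable, understating their dependence. Both caveats argue for
  reading TET/DET output as ranking, not as calibrated significance.

## Compound cluster analysis (CCA)

`cluster_compounds()` runs k-means on fingerprint bit vectors treated as
0/1 reals with Euclidean distance — squared Euclidean on bits is a
linear transform of Hamming distance, so "structurally similar" is
preserved; Tanimoto k-medoids would be a defensible alternative but is
out of scope. Initialization is k-means++ with 10 restarts, all seeded
deterministically from one master seed; the lowest within-cluster sum of
squares wins, ties broken by restart index, and identical inputs and
seed give byte-identical exports. `k` is user-chosen (no automatic
selection); `glance()` reports the mean silhouette width to guide it.

`build_cc_network()` scores every (cluster, class-term) pair with the
same odds-ratio/Fisher machinery ($R$ = cluster members, $R^C$ =
background minus cluster) and keeps edges with ES ≥ 1 bit and q ≤ 0.05
(BH-adjusted jointly over all pairs). Both thresholds are configuration,
not dogma — the network rendering convention is inherently a display
choice.

## The synthetic universe

`generate_universe()` builds everything the analytic modules consume,
deterministically per seed, with known planted truth:

* **10,000 compounds**, a **40-compound query** (the size of a typical
  deduplicated screening-hit set), **50 flag-based assays** of **2,000**
  tested compounds each.
* One planted assay draws hits at probability **0.3** inside the query
  and **0.001** outside; all other assays draw at 0.001 everywhere. The
  analytic expectation of the planted score,
  $\log_2(0.3/0.001) \approx 8.23$ bits, is written to the truth record.
* Every simulated assay screens a library *containing the query
  compounds* (plus a random background sample), mirroring the screening
  setting where the hit set comes from a library that assays also
  cover. This keeps the per-assay query denominator at $|Q|$; with
  uniformly sampled tested sets, null assays overlapping the query by
  only a handful of compounds produce pseudocount artifacts
  ($a = c = 0$ gives $\mathrm{ES} = \log_2(\mathrm{qc}_n/q_n)$) that
  say nothing about real enrichment.
* Fingerprints are generated directly as bit vectors in **3 planted
  blocks** (characteristic bits set with probability 0.9, others 0.1,
  256 bits) — no fake chemistry is invented for clustering tests; a
  small real-SMILES fixture covers the chemistry path separately.
* Disease and target trees are two-level, with one term ("viral
  infectious disease" by default) planted on one block's query members
  at rate 0.8; every compound also draws background annotations at rate
  0.02. The 0.8 and 0.02 rates are package choices: strong enough that
  the planted edge is unambiguous, sparse enough that the background
  resembles thinly annotated public interaction data.

What passing tests on this universe do **not** show: behavior on real
chemical space (correlated substructures, activity cliffs, scaffold
bias), on dose–response data, or on the heavily skewed assay-size
distributions of public repositories.

## Test and verification scales

The shipped suite checks the statistics against independent oracles
(brute-force arithmetic on 1,000 random tables; exhaustive
hypergeometric enumeration for all 2×2 tables with N ≤ 30; step-up BH on
200 random p-vectors), and the pipelines on 20-seed batches of the
default universe (planted-assay rank and score recovery, null FDR
calibration over 200 assays, cluster recovery at ARI ≥ 0.95). These
sizes were chosen to make the binomial noise bands explicit in each
assertion while keeping the whole suite around a minute of CPU.

## Known limitations

* Name-to-structure resolution, ID crosswalks, substructure/scaffold
  search and 3D conformers are out of scope; inputs arrive as SMILES/SDF
  and pre-mapped id tables.
* Open Babel descriptor values (logP especially) differ from other
  toolkits'; QED absolute values inherit that, and the bundled alert set
  is deliberately small.
* OBO parsing is not implemented; trees ship as parent–child TSV.
* Tree-enrichment p-values are pair-level (see caveats above).
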