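# compset

Set-wise analytics for collections of small molecules — typically
high-throughput screening hits. A hit list alone says nothing about
targets or mode of action; what its compounds' *known* annotations
(bioassay activities, target interactions, disease indications)
collectively concentrate on often does. compset provides:

* **Compound registry** — SMILES/SDF structures normalized (isotopes
  stripped, charges neutralized, explicit H removed) and deduplicated on
  the standard InChIKey, so salts and isotope labels of one molecule
  become one record; Open Babel descriptors (MW, logP, TPSA, HBD/HBA),
  Lipinski filtering, QED drug-likeness, FP2 path fingerprints, and
  Tanimoto similarity search.
* **Hit calling** — per-assay hit sets from active/inactive flags where
  available, otherwise the union of a Z-score criterion and a
  top-percentile criterion.
* **CSEA (compound set enrichment analysis)** — *hit-enriched assays*
  scored by the log2 likelihood ratio

  ES_HEA = log2( (|Q∩H| / |Q^C∩H|) / (|Q| / |Q^C|) ),

  and *target / disease enrichment trees* scored by the log2 odds ratio
  on compound–entity interaction pairs aggregated over each ontology
  term and its descendants; one-sided Fisher exact p-values with
  Benjamini–Hochberg FDR.
* **CCA (compound cluster analysis)** — k-means (k-means++, seeded,
  restarted) on fingerprints, each cluster linked to the annotation
  classes its interactions are enriched in, exported as a GraphML
  cluster–class network.
* **Synthetic universes** — a deterministic generator with planted
  enrichments (hit-enriched assay, annotated fingerprint block) and an
  analytic truth record, so every pipeline is testable end to end.

All user-facing functions take and return tibbles and compose with the
pipe; fitted results have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(compset)

# registry: aspirin + its acetate anion merge into one record
reg <- standardize(c(pc1 = "CC(=O)Oc1ccccc1C(=O)O",
                     pc2 = "CC(=O)Oc1ccccc1C(=O)[O-]",
                     pc3 = "CCO")) |>
  merge_registry() |>
  compute_properties()
reg[, c("merge_key", "n_members", "mw", "logp", "qed")]
#> # A tibble: 2 × 5
#>   merge_key                   n_members    mw     logp   qed
#>   <chr>                           <int> <dbl>    <dbl> <dbl>
#> 1 BSYNRYMUTXBXSQ-UHFFFAOYSA-N         2 180.   1.31    0.800
#> 2 LFQSCWFLJHTTHZ-UHFFFAOYSA-N         1  46.1 -0.00140 0.392

# a synthetic screening universe with one planted hit-enriched assay
u   <- generate_universe(synth_config(seed = 7))
hea <- assign_hits(u$assays) |> (\(h) run_hea(u$query, h))()
head(tidy(hea)[, c("rank", "assay_id", "a", "b", "c", "d", "es", "q")], 3)
#> # A tibble: 3 × 8
#>    rank assay_id     a     b     c     d    es        q
#>   <int> <chr>    <int> <int> <int> <int> <dbl>    <dbl>
#> 1     1 ASSAY01     14    26     3  1957  7.84 4.24e-21
#> 2     2 ASSAY09      1    39     1  1959  5.61 9.81e- 1
#> 3     3 ASSAY29      0    40     0  1960  5.61 1   e+ 0
```

The planted assay (`ASSAY01`, hit probability 0.3 inside the 40-compound
query vs 0.001 background) ranks first: 14 of its 40 tested query
compounds are hits against 3 of 1,960 background compounds, 7.84 bits of
enrichment, FDR-significant; the runners-up are pseudocounted zero-hit
assays whose scores carry q ≈ 1. `run_tree_enrichment()` and
`build_cc_network()` continue the same universe into disease-term
enrichment and the cluster network (see the vignette in `vignettes/`).

A thin command-line front end covering the same steps ships as
`inst/scripts/cset` (subcommands `standardize`, `assign-hits`, `csea`,
`cca`, `setops`, `filter`, `simulate`).

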