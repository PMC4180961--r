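# cnvmech

Mechanism classification of deletion copy-number variants (CNVs) from
chromatin domain architecture and phenotype-ontology similarity.

## The problem

Large genomic deletions can cause congenital disease in two fundamentally
different ways. The classical reading is a **gene-dosage effect (GDE)**:
haploinsufficiency of one or more genes inside the deletion. But deletions
that remove a **topological domain boundary (TDB)** — the insulating region
between two topologically associating domains — can also rewire regulation
without deleting any dosage-sensitive gene: a tissue-specific enhancer from
one domain gains access to a developmental gene in the formerly separate
domain (**enhancer adoption**, here called **TDBD** for
topological-domain-boundary disruption). Distinguishing these mechanisms
matters for interpreting patient CNVs, because the phenotypically relevant
gene may lie *outside* the deletion.

`cnvmech` is a reusable R implementation of a desk pipeline for this
question, aimed at researchers in regulatory genomics and clinical genome
interpretation. It provides:

* a rooted-DAG phenotype ontology with annotation propagation and
  corpus-specific **information content** `IC(t) = -ln p_t`, where `p_t` is
  the fraction of annotated entities carrying term `t` after propagation;
* Resnik-style patient–gene similarity: the **phenomatch score** of a gene
  `g` with term set `T_g` against a patient's propagated term set
  `annot_j`,

  `S_g = Σ_{t_g ∈ T_g} max{ IC(t) : t ∈ anc(annot_j) ∩ anc(t_g) }`,

  and the **phenogram score** `S_PG = max_{g ∈ G} S_g` of a genomic region;
* target-term assignment of each patient to one of ten tissue-linked
  phenotype branches via `argmax_i Σ_{t ∈ desc(T_i) ∩ annot_j} IC(t)`
  (patients with no branch overlap are unassigned; tied maxima are
  ambiguous and excluded);
* tissue-specific DNase I hypersensitive site (CTS-DHS) ranking from
  200-bp window read counts: normalised log counts, pooled within-tissue
  standard deviation `s`, and the regularised t-statistic

  `t_j = (X̄_j − X̄) / ( sqrt(1/m + 1/n_j) · (s + s₀) )`,

  with `s₀` the genome-wide mean of `s`; plus ubiquitous-DHS ranking,
  split-half reproducibility (correspondence-at-the-top) curves and
  `1 − cor` sample clustering distances;
* interval geometry: boundaries are inter-domain gaps of at most 400 kb,
  adjacent regions run from each breakpoint to the end of its domain
  (400-kb fallback where no domain contains the breakpoint), plus the fixed
  400-kb flank control for deletions that disrupt no boundary;
* the classification lattice per deletion: **TDBD evidence** = the deletion
  completely covers a boundary and a target-tissue enhancer and a
  target-annotated gene flank it on *opposite* sides; **GDE evidence** =
  within-deletion phenogram score above zero; TDBD evidence with
  `S_adjacent > S_within` gives `TDBD_only`, otherwise `TDBD_GDE`; GDE
  evidence alone gives `GDE`; neither gives `unexplained`;
* null models: phenotype shuffling across target groups, gene-annotation
  permutation, length-preserving random placement with a Wilcoxon rank-sum
  comparison, and plain empirical P values (`#{null ≥ observed}/n`);
* a synthetic-data generator that plants TDBD / mixed / GDE / benign
  deletions with known ground truth so the whole pipeline is testable
  without any restricted patient data.

## Worked example

```r
library(cnvmech)

cfg <- simulation_config(seed = 7, n_patients = 120, domains_per_chrom = 120)
sim <- generate_all(cfg)

pat     <- propagate(sim$dag, sim$patient_annotations)
ic_pat  <- information_content(sim$dag, pat, "patients")
ic_gene <- information_content(sim$dag,
                               propagate(sim$dag, sim$gene_annotations),
                               "genes")

calls <- classify_cohort(sim$cohort, pat, sim$arch, sim$dag,
                         sim$gene_annotations, ic_pat, ic_gene, sim$targets)
cohort_summary(calls)$counts
#>    TDBD_only     TDBD_GDE          GDE  unexplained not_assessed
#>           12           24           72           12            0

head(calls[, c("patient_id", "category", "target", "s_within", "s_adjacent")], 4)
#>   patient_id  category target s_within s_adjacent
#> 1      P0001 TDBD_only   T:04        0  18.739819
#> 2      P0002 TDBD_only   T:09        0  18.034249
#> 3      P0003 TDBD_only   T:08        0  20.798641
#> 4      P0004 TDBD_only   T:03        0   9.773641

run_phenotype_shuffle_test(sim$cohort, pat, sim$arch, sim$dag,
                           sim$gene_annotations, ic_pat, ic_gene,
                           sim$targets, n_reps = 1000, seed = 7,
                           rate = "TDBD_or_mixed")
#> permutation test (TDBD_or_mixed): observed rate 0.3, null mean 0.04785,
#> empirical P < 0.001 (1000 reps)
```

The cohort was planted with 10% TDBD / 20% mixed / 60% GDE / 10% benign
deletions at zero annotation noise, and the classifier recovers exactly that
mixture; the shuffle test shows the boundary-disruption signal vanishes when
phenotypes are reassigned across target groups. The `TDBD_only` rows have
`s_within = 0` (no phenotypically relevant gene was deleted) but a large
`s_adjacent` — the signature of enhancer adoption.

A file-based run of the same pipeline:

```r
simulate_bundle(cfg, "simdata")                   # writes BED/TSV inputs
cnvmech_cli(c("run",
  "--ontology", "simdata/ontology.tsv",   "--targets",    "simdata/targets.tsv",
  "--gene-annotations", "simdata/gene_annotations.tsv",
  "--domains",  "simdata/domains.bed",    "--genes",      "simdata/genes.bed",
  "--enhancers","simdata/enhancers.bed",  "--chrom-sizes","simdata/chrom.sizes",
  "--cohort",   "simdata/cohort.tsv",     "--out",        "results"))
```

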