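# gctomics

Integrative miRNA / mRNA / copy-number / survival analysis of pediatric
central-nervous-system germ-cell-tumor (GCT) cohorts.

## The problem

Intracranial pediatric GCTs divide clinically into a good prognostic group
(GPG: germinomas, mature teratomas) and the nongerminomatous malignant tumors
of the intermediate/poor prognostic groups (`IPG_PPG`). The two groups differ
in overall survival, in their miRNA and mRNA expression programs, in how close
they sit to embryonic stem cells (ESC) in expression space, and in recurrent
chromosomal losses. `gctomics` implements the full integrative analysis
linking those layers, as a tested R package, for anyone who has (or wants to
simulate) per-group expression matrices, SNP-array probe tracks, target
predictions and survival records.

## What is inside

| Stage | Statistic | Functions |
|---|---|---|
| miRNA signatures | two-sided pooled Student's *t* + fold change ≥ 2, p < 0.05 | `student_t`, `fold_change`, `mirna_signatures` |
| mRNA signatures | empirical-Bayes moderated *t*, Storey pFDR q < 0.001 | `moderated_t`, `storey_qvalues`, `mrna_signatures` |
| ESC proximity | inter-group average-linkage Euclidean distance ± SE | `group_distance`, `pca_embedding`, `mds_embedding`, `average_linkage_tree` |
| miRNA–target integration | anti-correlated pairs + per-miRNA Fisher exact enrichment | `anti_correlated_pairs`, `fisher_exact_2x2`, `mirna_enrichment`, `multi_target_summary`, `annotate_intragenic` |
| Copy number | median-filter/threshold/run-length LRR-BAF caller, sweep-line recurrent regions, expression integration | `call_copy_number`, `recurrent_regions`, `aberration_table`, `features_in_region`, `integrate_cnv_expression` |
| Over-representation | right-tail hypergeometric, BH alongside, cytoband positional sets | `overrepresentation`, `enrich_collection`, `cytoband_sets` |
| Survival | Kaplan–Meier product limit, log-rank | `kaplan_meier`, `km_rate_at`, `logrank` |
| Simulation | synthetic cohorts with planted ground truth | `cohort_config`, `generate_cohort`, `write_cohort` |
| Orchestration | config-driven end-to-end run with a JSON report | `run_config`, `run_pipeline` |

The moderated *t* shrinks each feature's pooled variance `s²` (on `d` df)
toward an ensemble prior `(d₀, s₀²)` fitted by method of moments on `log s²`:

    s̃² = (d₀·s₀² + d·s²) / (d₀ + d),   t̃ = Δ / (s̃·√(1/nₐ + 1/n_b)),

with two-sided p on `d₀ + d` df; the ESC-proximity statistic is the mean of
all |A|·|B| pairwise Euclidean distances between two groups over a signature
feature set, with SE = sd(pairwise)/√(|A|·|B|). Details, conventions and
design rationale are in the methods vignette
(`vignettes/gct-integrative-pipeline.Rmd`).

## Worked example

```r
library(gctomics)

ch <- generate_cohort(cohort_config(seed = 42))   # synthetic study-design cohort

mi <- mirna_signatures(ch$mirna, ch$groups)       # t-test + 2-fold filter
mr <- mrna_signatures(ch$mrna, ch$groups)         # moderated t + q < 0.001
mi$GPG; mi$IPG_PPG; mr$GPG; mr$IPG_PPG
#> SignatureSet: 2 features up in GPG
#> SignatureSet: 19 features up in IPG_PPG
#> SignatureSet: 400 features up in GPG
#> SignatureSet: 290 features up in IPG_PPG

sig <- union(signature_features(mr$GPG), signature_features(mr$IPG_PPG))
group_distance(ch$mrna, ch$groups, "GPG", "ESC", sig)$mean_distance      # 27.87
group_distance(ch$mrna, ch$groups, "IPG_PPG", "ESC", sig)$mean_distance  # 26.22

segs <- lapply(ch$snp, call_copy_number)
recurrent_regions(segs, ch$groups, "IPG_PPG", "loss", 3, ch$annot$cytobands)
#>   chromosome    start       end state   group support           samples      cytoband
#> 1       chr4 75848791 130628473  loss IPG_PPG       3 NGM_1,NGM_3,NGM_5 4q13.3-4q28.3

lr <- logrank(ch$surv, "GPG", "IPG_PPG")
round(c(chisq = lr$chi_square, p = lr$p), 5)
#>    chisq        p
#> 16.27936  0.00005
```

Reading the output: the miRNA branch recovers the planted 2 GPG-enriched and
19 IPG_PPG-enriched miRNAs and the mRNA branch the 400/290 signature genes;
the malignant group sits closer to the ESC reference (26.22 vs 27.87
expression-space units) on the signature-restricted distance; the copy-number
stage finds the hemizygous 4q-analog deletion shared by 3 of the 5 malignant
SNP samples, labelled `4q13.3-4q28.3`; and `integrate_cnv_expression()`
reports exactly the 6 planted in-deletion genes as dosage-consistently up in
the non-deleted group. The log-rank test separates the two survival curves
(10-year survival 0.75 vs 0.38 in this cohort).

The same stages run from files (TSV matrices, BED-style annotation, GMT sets,
SNP probe tables, survival CSV) via `run_config(synthetic = FALSE,
paths = list(...))`, and `run_pipeline()` writes every stage table plus a
machine-readable `report.json`.

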