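# pharmsurv

Population-level pharmacosurveillance for companion-animal veterinary
practice. Electronic health records from sentinel networks of veterinary
practices record everything supplied at a consultation as free text, with no
shared nomenclature; `pharmsurv` provides the analysis chain that turns
those records into population prescribing statistics:

1. **Rule-based text mapping** — exclusion regexes (diagnostic tests,
   syringes, refunds) followed by literal prescription-identifying strings
   map practitioner-defined product descriptions onto a drug taxonomy of
   pharmaceutical agents, classes (PC) and families (PF), each agent tagged
   as veterinary-authorised, human-authorised (prescribed under the
   veterinary cascade) or generic.
2. **Frequency estimation** — consultation-, animal- and family-level
   prescription frequencies and rates per 10,000 consultations, with
   cluster-bootstrap percentile confidence intervals that respect clustering
   within sites and of animals within practices.
3. **Prescription Diversity (PD)** — an adaptation of the Simpson diversity
   index to prescribing. For class counts *np* within one family (total
   *NP*, per practice *i*):

   PD*ᵢ* = 1 − Σ *np*(*np* − 1) / (*NP*(*NP* − 1))

   the probability that two prescriptions drawn without replacement from the
   family belong to different classes. A family whose *k* classes are
   prescribed evenly has a natural ceiling near 1 − 1/*k* (0.75 for four
   classes at *NP* = 2000, 0.88 for eight), so PD is compared between
   practices within a family, never across families. A quintile benchmarking
   matrix cross-tabulates practices by prescription frequency and PD.
4. **Co-prescription networks** — families prescribed together in one
   consultation form a weighted graph (nodes sized by prescriptions, edges
   by co-prescription counts), sparsified by a 0.5% node-share rule and a
   strict edge-mean rule, then partitioned into co-prescription groups by
   seeded, consensus label propagation.
5. **Comparative statistics** — pairwise Wilcoxon rank-sum tests with
   Bonferroni correction between species, and tie-corrected Kendall
   correlations with t-approximation p-values.

Because real sentinel-network extracts are confidential, the package ships a
synthetic EHR generator (`synth_config()` / `generate_dataset()`) that
emulates the structure of such data — practices with sites, species mix,
ten presenting complaints, noisy product text, and three planted
co-prescription blocks (preventive care, treatment, euthanasia) — together
with the ground truth needed to validate every stage.

## Worked example

```r
library(pharmsurv)

compute_pd(c(800, 400, 400, 400))
#> [1] 0.7203602        # reported as 0.72

cfg <- synth_config(seed = 7)   # 50 practices, 5000 animals, ~40k consults
out <- run_pipeline(cfg, seed = 7, n_boot = 200)

out$mapping
#>   n_unique_descriptions n_excluded n_matched n_unmatched
#> 1                  5867          4      5850          13

out$frequency
#> 0.6560 (95% CI 0.6359-0.6753; 200 bootstrap replicates over 75 site_id clusters)

out$pd_medians
#>   species median_pd n_practices
#> 1 cat         0.719          50
#> 2 dog         0.708          50
#> 3 rabbit      0.733          50

round(out$coprescription_rate, 3)
#> [1] 0.443

as.data.frame(out$groups)
#>                   pf group
#> 1  anti-inflammatory     1
#> 2         antibiotic     1
#> ...
#> 9         euthanasia     3
#> ...
#> 13           vaccine     2
```

Reading the output: 65.6% of booked consultations recorded at least one
prescription (the interval is the wider of the site-level and
animal-within-practice cluster bootstraps); median antibiotic PD per species
sits near 0.71–0.73 under the generator's class mixes; 44.3% of prescribing
consultations co-prescribed across families; and label propagation recovers
exactly the three planted blocks — the treatment families (group 1), the
preventive vaccine/parasiticide families (group 2), and euthanasia isolated
on its own (group 3), the pattern expected of healthy, unhealthy and
end-of-life consultations.

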