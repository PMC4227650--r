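# promscreen

Selection of stress-inducible promoters from gene-expression compendia,
for plant molecular farming.

## The problem

Producing a phytotoxic recombinant peptide (an antimicrobial peptide, a
cytotoxin) in a stably transformed plant only works if the transgene is
*silent* while the plant is being made — through callus induction,
Agrobacterium infection, antibiotic selection, regeneration, embryo
development and germination — and *strongly expressed* on demand
afterwards. The deciding property of a candidate promoter is therefore
not its induced strength but its **basal activity across the
transformation-relevant tissues**, which must sit below an empirically
known toxicity threshold.

`promscreen` implements an in-silico strategy for finding such promoters
in normalized expression compendia (microarray or RNA-seq summaries):

1. **Induction screen** — per probe, with control mean
   $\bar{x}_C$ and induced mean $\bar{x}_I$ over replicates, compute the
   difference $\Delta = \bar{x}_I - \bar{x}_C$ and fold
   $F = \bar{x}_I / \max(\bar{x}_C, \varepsilon)$; keep probes with
   $\Delta$ above a threshold (default 5 500 normalized units), then
   collapse probes to genes (max-induced representative).
2. **Basal profiling** — mean expression over a panel of 14
   transformation-relevant tissues, plus control/induced seedling levels
   and per-stress induction folds.
3. **Anchor classification** — candidates are classed against two anchor
   genes whose in-planta behaviour is known: an Hsp82-like anchor (basal
   levels tolerated by phytotoxic cargo; its induced level is the minimum
   useful induction) and an Hsp18-like anchor (basal levels that still
   permit a reporter but not a toxin). With panel mean $m$, control level
   $c$, induced level $i$ and anchors $(m_{82}, c_{82}, i_{82})$,
   $(m_{18}, c_{18}, i_{18})$, all comparisons inclusive:
   * `NOT_INDUCIBLE` if $i < i_{82}$ or $c > c_{18}$;
   * `SUITABLE` if $m \le m_{82}$;
   * `MARGINAL` if $m \le m_{18}$;
   * `UNSUITABLE` otherwise.
4. **Specificity check** — a candidate heat-shock promoter must not
   respond to cold, salt or drought (fold < 2 against matched controls).
5. **Prospective screen / ranking** — profile every gene, pre-screen by
   $i \ge i_{82}$ and $c \le c_{18}$, classify survivors and rank.

The package also implements the validation statistics used alongside such
screens — efficiency-corrected qPCR relative expression
($E_\mathrm{ref}^{Ct_\mathrm{ref}} / E_\mathrm{tgt}^{Ct_\mathrm{tgt}}$),
geNORM reference-gene stability $M$, transgene copy-number calls from
transgene/endogene ratios, and transformation efficiency normalized to an
empty-vector control with a 30-fold workability rule — and a fully
deterministic synthetic-compendium generator with planted ground truth,
so the whole pipeline is testable without any external download.

## Worked example

```r
library(promscreen)

# A synthetic two-condition compendium emulating a summarized
# control vs heat-shock seedling experiment (all values planted):
sim   <- generate_hs_compendium()
stats <- compute_induction_stats(sim$compendium, control = "control",
                                 induced = "heat", gene_map = sim$gene_map)
surv  <- screen_candidates(stats, screen_criteria(difference_min = 5500))
nrow(surv)                        # 19 probes survive the difference screen
nrow(collapse_to_genes(surv))     # ... collapsing to 16 genes
max(stats$fold)                   # top induction: 615-fold (probe AK063751.1)
```

The strongest survivors, one representative probe per gene:

```
  probe_id   gene_id    mean_control mean_induced  fold difference
1 AK071240.1 Os.hsp18            450        12000 26.7       11550
2 AK071613.1 AK071613           6200        16300  2.63      10100
3 AU165294   AU165294.g          400         9800 24.5        9400
```

`difference` is the heat-minus-control mean in normalized fluorescence
units — the primary screening statistic; `fold` alone is misleading
(AK071613 has a huge difference but only 2.6-fold induction because its
basal level is high).

Classification end to end on a multi-tissue panel compendium with the two
anchor genes planted at their published levels:

```r
panel <- generate_compendium(c(anchor_archetypes(), default_archetypes()),
                             noise_sd_log = 0, seed = 7)
rep <- run_pipeline(pipeline_config(
  compendium = panel$compendium,
  criteria   = screen_criteria(difference_min = 0.5),
  anchors    = default_anchors(scale_tag = "synthetic")))
glance(rep)
#>   n_candidates n_suitable n_marginal n_unsuitable n_not_inducible n_specific
#> 1           37          6         11            0              20         27
tidy(rep)[tidy(rep)$gene_id %in% c("Os.hsp82", "Os.hsp18"), ]
#>   rank  gene_id panel_mean control_level induced_level    class specific
#> 1    6 Os.hsp82      0.033         0.001          0.65 SUITABLE     TRUE
#> 2   17 Os.hsp18      0.073         0.052          1.19 MARGINAL     TRUE
```

The hsp82-like anchor classifies `SUITABLE` and the hsp18-like anchor
`MARGINAL` — mirroring the experimental outcome that only the
lower-basal promoter yielded viable plants carrying a phytotoxic
transgene, while both sufficed for a harmless reporter.

`plot_induction()`, `plot_heatmap()` (clustered log-scale basal profiles),
`plot_timecourse()` and `autoplot()` on a report give the standard
figures. A thin command-line wrapper with subcommands (`screen`,
`prospect`, `run`, `cluster`, `simulate`, `qpcr`, `copynum`, `transeff`)
is installed at `inst/cli/promscreen`.

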