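# coexnet

Weighted gene co-expression network analysis for matched two-condition
time-course expression studies: network construction, topological-overlap
module detection, eigengene/kME membership, permutation-based module
preservation between conditions and across process stages, and hub-gene
prioritization.

## The scientific problem

Differential-expression analysis of a perturbation time course (the
motivating setting is hepatocyte transcriptomes after two-thirds partial
hepatectomy versus sham-operated controls in rat) yields flat gene lists
and ignores the correlation structure that organizes genes into functional
programs. `coexnet` instead builds, for each condition, a fully connected
weighted network from expression correlations and asks which co-expression
modules exist, which persist between conditions, when during the process
they are active, and which genes sit at their centres.

The core quantities, in the field's standard notation:

- **Adjacency (connection strength).** From the Pearson correlation matrix,
  an unsigned soft-thresholded adjacency `a_ij = |cor(x_i, x_j)|^β`, with
  the power β chosen by the scale-free topology criterion (smallest β whose
  connectivity distribution fits a power law with R² above a target).
- **Topological overlap.**
  `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
  `l_ij = Σ_u a_iu a_uj` and connectivity `k_i = Σ_j a_ij`; `1 − TOM` is
  the clustering dissimilarity. Modules are branches of the average-linkage
  dendrogram, cut with a dynamic (adaptive) tree cut and refined by
  reassigning each gene to the module eigengene it correlates with most
  strongly (genes with `|kME| < 0.3` everywhere stay unassigned).
- **Module eigengene and kME.** The first singular vector of a module's
  standardized expression summarizes the module; `kME_im = cor(x_i, ME_m)`
  measures membership, and the maximal-|kME| gene is the module's hub.
- **Module preservation.** For a module found in one network, its density
  (mean intramodular adjacency) and connectivity pattern (correlation of
  intramodular connectivity) are measured in the other network and
  standardized against permutation nulls of random same-size gene sets:
  `Zsummary = (Zdensity + Zconnectivity) / 2`. `Zsummary > 10` is strong
  evidence of preservation, `2 < Zsummary < 10` weak, `Zsummary < 2` none —
  a module detected in the test condition with no evidence in the reference
  is condition-specific.
- **Stage-wise preservation.** The same Z statistics computed against
  networks rebuilt from stage-restricted samples (priming 2–6 h,
  proliferative 6–72 h, termination 72–168 h) localize a module's activity
  in time.

A synthetic-data generator plants co-expression modules with graded
membership strength and controlled preservation (preserved / weak /
test-specific) in matched two-condition designs, so the whole pipeline is
testable without any microarray download.

## Worked example

```r
library(coexnet)
library(dplyr)

cfg <- simulation_config(
  bind_rows(
    module_spec("cellcycle", 40, membership_low = 0.7, membership_high = 0.95,
                preservation = "specific_to_test"),
    module_spec("metabolism", 50, membership_low = 0.7, membership_high = 0.95),
    module_spec("stress", 35, membership_low = 0.7, membership_high = 0.95,
                preservation = "weak")
  ),
  n_background_genes = 150, noise_sd = 0.35, rng_seed = 42
)
study <- simulate_two_condition_dataset(cfg)

net_test <- build_network(study$expr$test, power = 6)
net_ref  <- build_network(study$expr$reference, power = 6)
modules  <- detect_modules(study$expr$test, net_test$tom)
pres     <- module_preservation(net_test, net_ref, modules,
                                n_perm = 200, seed = 1)
tidy(pres)
```

```
# A tibble: 3 × 7
  module    module_size z_density z_connectivity z_summary evidence specific
  <chr>           <int>     <dbl>          <dbl>     <dbl> <chr>    <lgl>
1 turquoise          73    184.            2.62      93.3  strong   FALSE
2 blue               64     -2.57         -5.68      -4.12 none     TRUE
3 brown              51      1.54          0.634      1.09 none     TRUE
```

The three detected modules recover the three planted ones (labels follow
size rank). The preserved "metabolism" module (turquoise) shows strong
evidence in the reference network; the planted test-specific module (blue)
has no evidence there and is flagged `specific` — the pattern that marks a
process-specific program such as a proliferation module appearing only
after hepatectomy. The weakly preserved module (brown) lands at the bottom
of the evidence scale: halving the loadings puts such modules near the
none/weak boundary at these sample sizes.

Hub genes are the maximal-|kME| members:

```r
hub_genes(modules, modules$kme,
          gene_significance(study$expr$test, study$expr$reference))
```

```
# A tibble: 3 × 6
  module    hub             kme_own     gs p_value runner_up
1 turquoise metabolism_g008   0.951 0.692    0.492 metabolism_g010
2 blue      cellcycle_g024    0.971 0.0707   0.944 cellcycle_g036
3 brown     stress_g025       0.964 0.123    0.903 stress_g001
```

Every hub is a planted module member with kME above 0.95, mirroring how
strongly connected intramodular genes (kME ≈ 0.94–0.97) are reported as
candidate regulators. `stagewise_preservation()` adds the module × stage
Zsummary table, `export_edge_list()` writes Cytoscape-importable edge and
node tables (edges with connection strength > 0.3 by default), and
`run_pipeline()` executes everything from a single YAML/JSON or list
configuration, writing TSVs, a JSON manifest and a log. A thin command-line
front end is installed at `exec/coexnet` (`coexnet simulate|pipeline
--config cfg.yaml --out dir/`).

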