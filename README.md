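# atf3net

Deterministic ODE models of the **Atf3–Egr1 immediate-early-gene
negative-feedback network** in cardiomyocytes stimulated with endothelin-1,
for systems biologists who want to test, quantitatively, which mechanisms can
switch an immediate-early gene off again.

Atf3 (activating transcription factor 3) is induced within minutes via
ERK1/2, represses the Egr1 promoter (which makes the Egr1 response
transient), and is itself shut down over ~4 h by mechanisms that the package
explores as nested model variants:

| Variant | Mechanism added |
|---|---|
| `BASE` | ERK1/2 (de)activation, reversible phosphorylation of promoter-bound activator TFs, competitive Atf3 repression of Egr1 |
| `EXT1_AUTOREP` | Atf3 binds its own promoter (autorepression) |
| `EXT2_RTF` | RSK-phosphorylated repressor TF competes at the Atf3 promoter |
| `EXT3_ITF` | de novo inhibitory TF, transcribed downstream of RSK |
| `EXT4_MIRNA` | RSK-driven miRNAs sequester Atf3 mRNA into a translationally silent, degradable complex |
| `EXT5_COMBINED` | ITF and miRNA arms together |

All kinetics are mass action. For a promoter `P` with bound activator `X`
toggled by ERK-P and a repressor `R`,

    P·X  + ERK-P  -> P·X* (rate k  [ERK-P][P·X]),   P·X* -> P·X (rate k-)
    P·X(*) + R   <-> P·R  (association 1e5 (Ms)^-1, slow reversal)
    mRNA: d[m]/dt = k_tx [P·X*] - d_m [m],  protein: d[A]/dt = k_tl [m] - d_A [A]

and in the miRNA arm, free mRNA and miRNA form a silent complex
(`k19 = 1e5 (Ms)^-1`, `k-19 = 5e-5 s^-1`) whose decay (`d8`, scenario
multipliers 1/2/4) destroys the mRNA and recycles the miRNA. Conservation
(ERK, RSK, each promoter's occupancy states) holds exactly by construction
and is asserted along every trajectory.

## Worked example

```r
library(atf3net)
tc <- simulate_model("BASE", duration_h = 4)      # step stimulus at t = 0
extract_features(time_min(tc), observable(tc, "erk_p"),
                 query_times = c(30, 60))
#> Profile features: peak 34.72 at 2.5 min; return to <=10% at 38 min
#>   fraction of peak elevation at (min):
#>     30     60
#> 0.1646 0.0258
```

ERK-P (34.7 nM of the 40 nM pool) peaks 2.5 min after stimulation and has
declined by 97% of its peak elevation at 60 min — the measured profile is
"maximal at ~3 min, ~90% decline by 1 h". Egr1 mRNA returns to 10% of its
peak elevation at 92 min (measured: back to basal by ~2 h), and only because
Atf3 represses it:

```r
reproduce_paper()[, c("scenario", "egr1_frac_2h", "atf3_protein_frac_4h",
                      "atf3_mrna_total_frac_4h")]
#>              scenario egr1_frac_2h atf3_protein_frac_4h atf3_mrna_total_frac_4h
#> 1                base       0.0240              0.35045                  0.3372
#> 2    base_no_feedback       0.9742              0.35044                  0.3372
#> 4  ext1_tight_binding       0.6684              0.19105                  0.1790
#> 8           ext4_d8x1       0.0500              0.03667                  0.3372
#> 12          ext4_d8x4       0.0509              0.02158                  0.0576
#> ...
```

Reading the columns as fractions of peak elevation: without feedback Egr1
stays at 97% of its peak at 2 h; a 10^6-fold tighter Atf3–own-promoter
interaction (`ext1_tight_binding`) suppresses Atf3 but *loses* the acute
Egr1 inhibition (0.67 at 2 h) — autorepression is self-defeating; the miRNA
variant terminates Atf3 protein at every complex-degradation rate (0.04 at
4 h even with no degradation enhancement), and a 4-fold enhancement also
makes total Atf3 mRNA transient (0.058 at 4 h). The
`matches_reported_conclusion` column is `TRUE` for all 13 scenarios.

Other entry points: `default_parameters()` / `apply_override()` (provenance-
tagged parameter sets), `calibrate_submodel()` (feature-based least-squares
replacing fit-by-eye), `local_scan()` / `rank_sensitivities()` (10- and
100-fold one-at-a-time sensitivity analysis), `generate_dataset()` /
`canonical_shapes()` (experimental-style replicate tables), and
`run_scenario()` / `scenario_config()` with YAML round-tripping. A thin
command-line wrapper lives in `inst/cli/atf3net-cli.R`.

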