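# phglv

pH-dependent generalized Lotka–Volterra (gLV) simulation of bacterial
communities under temporal environmental fluctuations.

The package is for microbial ecologists asking a concrete question about
low-diversity, culturable communities such as the human nasal microbiota:
**does a temporally fluctuating environment (here, pH) change which
species stably coexist, and by how much does it move the composition?**
It provides the full in silico pipeline: characterize strains by their
pH-dependent growth rate `r_i(p)` and carrying capacity `K_i(p)`, infer
pairwise interaction coefficients from supernatant assays, assemble
stable multi-strain communities by simulated enrichment, expose them to
controlled pH fluctuations, and quantify the composition deviation.

## The model

Each strain follows a gLV equation with continuous dilution:

    dS_i/dt = r_i(p) * [1 - (S_i - gamma_i) / K_i(p)] * S_i - delta * S_i
    gamma_i = sum_{j != i} c_ij * S_j

with `c_ii = -1` (complete niche overlap), `c_ij in (-1, 0)` partial
overlap, `c_ij < -1` inhibition beyond competition, `c_ij > 0`
facilitation; `c_ij = (K_ij - K_i) / K_j` from the capacity `K_ij` that
strain `i` reaches in spent medium of `j`.  The pH driver `p(t)` is
constant, sinusoidal `p0 + dpH * sin(2 pi f_pH t)`, or a two-level random
telegraph.  Composition deviations are Bray–Curtis dissimilarities
`1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))` between the fluctuating and
the fixed-pH run of the same community.  Closed-form fast- and
slow-fluctuation limits (a WKB envelope whose log-amplitude falls as
`1/f`, and a quasi-static linear solve `[C] S = b` with
`b_i = (delta - r_i) K_i / r_i`) are built in as oracles against the
simulator (`verify_limits()`).

## Worked example

```r
library(phglv)

panel <- generate_base_panel(panel_spec(seed = 11))
panel
#> <base_panel> 6 species; 3 facilitation coefficients

# sample 20-strain assemblages, enrich to stable communities at pH 6.3,
# keep those robust to +/-50% dilution-rate changes
ens <- assemble_ensemble(panel, 50, sim_config(), seed = 7)
attr(ens, "counts")
#> assemblages      stable    filtered
#>          50          40          36

# expose each community to sinusoidal pH fluctuations at f_pH = 0.2/h
amp <- amplitude_sweep(ens, c(0, 0.25, 0.5, 1), f_ph = 0.2, seed = 2)
amp
#> <experiment_summary> over 36 communities
#>   dph     median        mean frac_below  n
#>  0.00 0.00000000 0.000000000          1 36
#>  0.25 0.01114532 0.009859681          1 36
#>  0.50 0.03206578 0.028080451          1 36
#>  1.00 0.10576639 0.093414122          1 36
```

Reading the table: each row is one fluctuation amplitude `dph` (pH
units); `median`/`mean` summarize the Bray–Curtis deviation of each
community's cycle-averaged composition from its own fixed-pH reference
(0 = unchanged, 1 = completely different), and `frac_below` is the
fraction of communities deviating less than 0.2.  The zero-amplitude row
is exactly zero by construction; deviations grow with amplitude but stay
modest — on this synthetic panel every community stays below 0.2 even at
a fluctuation of a full pH unit, the robustness regime reported for
measured nasal strains.  `frequency_sweep()` shows the
complementary result: deviation peaks at intermediate frequencies and
vanishes in both the quasi-static and the fast-averaging limit.

Other entry points: `facilitation_group_comparison()` (competitive vs
cooperative communities, Mann–Whitney U), `niche_overlap_sweep()` /
`facilitation_prevalence_sweep()` (interaction-structure manipulations),
`richness_under_fluctuating_assembly()` (assembly under a fluctuating
environment), `load_panel()` / `load_config()` (externally measured
panels and JSON configs), and a CLI (`inst/cli/phglv`) with subcommands
`assemble`, `sweep-amplitude`, `sweep-frequency`, `compare-facilitation`,
`niche-overlap`, `fluctuating-assembly`.

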