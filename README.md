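# brokenrod

Time-resolved small-angle X-ray scattering (SAXS) analysis of ionotropic
polysaccharide gelation, built around the two-component **broken-rod Kratky
model**. The intended users are scattering practitioners following the
formation of Ca²⁺–alginate junction zones (or similar rod-cross-section
systems) frame by frame.

## The model

Over a q window where scattering is dominated by the rod cross-section, a
gelling sample is described in Kratky space (q²I(q) vs q) as a mixture of a
thin chain population and a thick junction-zone population:

    q²I(q) = q·k₁·[J₁(qR_c1)/(qR_c1)]² + q·k₂·[J₁(qR_c2)/(qR_c2)]² + const

with cross-sectional radii `R_c1 < R_c2` (nm), amplitudes `k₁, k₂ ≥ 0`
proportional to the component weight fractions (`w_i = k_i/(k₁+k₂)`), and a
Kratky-space constant. Each rod term peaks at `q·R_c = x* ≈ 1.3566` (the root
of `2x·J₀ = 3·J₁`), so a 2.6–3.0 nm junction zone produces the
experimentally observed Kratky maximum near `q ≈ 0.5 nm⁻¹`, while 0.2 nm
single chains rise linearly across the whole instrument window.

The package provides:

- `formfactor`: model evaluation, Kratky/intensity transforms, peak location
  (`kratky_model`, `intensity_model`, `kratky_peak`);
- `saxs_io`: plain-text profile and series I/O, buffer subtraction with
  uncertainty propagation, q-window masking (`read_series`,
  `subtract_buffer`, `mask_q`);
- `fitting`: bounded weighted least squares per frame, BIC selection between
  one and two components, warm-started series fits, replicate averaging
  (`fit_frame`, `select_components`, `fit_series`);
- `rdsim`: a 1D reaction–diffusion simulator of competitive ligand-exchange
  (CLEX) Ca²⁺ release coupled to gelation (`rd_simulate`, `roi_mean_gel`);
- `synthetic_data`: seeded generation of realistic frame series with known
  ground truth (`scenario`, `render_frames`, `write_fixture`);
- a command-line interface (`run_cli`, wrapped by
  `inst/scripts/brokenrod-cli.R`) with `generate`, `fit`, `simulate-rd` and
  `report` subcommands.

See `vignettes/broken-rod-saxs.Rmd` for the methods account.

## Worked example

```r
library(brokenrod)

# a fully gelled state: 0.9 nm chains + 2.9 nm junction zones, 80% junctions
p <- broken_rod_params(rc1 = 0.9, rc2 = 2.9, k1 = 0.2, k2 = 0.8, const = 0.002)
kratky_peak(p, 0.103, 3.26)
#> [1] 0.5444074

# simulate a gelation run (one frame / 5 s, plus a 10 h frame), then fit it
sim    <- render_frames(scenario("pH7.0"), times = c(seq(0, 45, by = 5), 36000), seed = 1)
frames <- lapply(sim$frames, subtract_buffer, buffer = sim$buffer)
tc     <- fit_series(frames)
tc[c(1, 3, 5, 11), c("time_s", "n_comp", "rc1_nm", "rc2_nm", "w2")]
#>    time_s n_comp rc1_nm rc2_nm    w2
#> 1       0      1  0.211     NA 0.000
#> 3      10      1  0.303     NA 0.000
#> 5      20      2  0.405  2.670 0.175
#> 11  36000      2  0.893  2.881 0.804
```

The fitted series reads exactly as the physics: at t = 0 a single thin
component (~0.2 nm, dispersed chains; BIC rejects a second component), a
thick ~2.7 nm junction-zone component appearing within tens of seconds, and
the equilibrated gel at 10 h reaching `R_c1 ≈ 0.9 nm`, `R_c2 ≈ 2.9 nm` with
~80% of the weight in junction zones.

The reaction–diffusion module reproduces the diffusion-limited kinetics at
the contact zone of the two CLEX solutions:

```r
res <- rd_simulate(rd_config())             # defaults: D = 0.78e-9 m²/s, κ = 1e4 /M/s
roi_mean_gel(res, 0,      50e-6)            # 50 µm ROI at the interface
#> [1] 0 0.0505 0.0505 0.0505 ... (saturated within the first 12 s output step)
roi_mean_gel(res, 200e-6, 50e-6)            # 50 µm ROI, 200 µm off-centre
#> [1] 0 0 0 0.0015 0.0246 0.0466 0.0505 ... (gel arrives ~40 s later)
```

Gel concentration is in moles of monomer per litre; 0.0505 M is complete
gelation of 1% w/v alginate.

## Command line

```sh
Rscript inst/scripts/brokenrod-cli.R generate --scenario pH7.0 --seed 1 --out fixture/
Rscript inst/scripts/brokenrod-cli.R fit --manifest fixture/manifest.csv \
        --buffer fixture/buffer.dat --out fits/
Rscript inst/scripts/brokenrod-cli.R simulate-rd --out rd/
Rscript inst/scripts/brokenrod-cli.R report --timecourse fits/timecourse.csv --out report/
```

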