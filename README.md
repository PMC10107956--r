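# suturefe

Finite-element analysis of cranial suture mechanics on synthetic skull
phantoms.

Cranial sutures are thin fibrocellular joints between skull bones,
three orders of magnitude more compliant than the surrounding cortical
bone (E ≈ 20 MPa vs ≈ 19 920 MPa). Whether and where they matter for
cranial load transfer is a standing question in skull biomechanics,
usually studied by running a finite-element model twice — once with
patent sutures, once with the sutures "fused" by assigning them bone
properties — and comparing the strain fields. `suturefe` implements
that whole experiment at desk scale for workflows that cannot carry a
multi-million-element micro-CT mesh: it generates a parametric,
tissue-labelled tetrahedral **skull phantom** (cortical and trabecular
bone, straight and interdigitated suture bands, tooth pegs with
periodontal-ligament sleeves), loads it with muscle forces derived from
architecture, solves the linear-elastic problem for both material
variants, and post-processes principal strains the way the craniofacial
FE literature does.

The quantitative core:

* **Muscle model** — physiological cross-sectional area
  `PCSA = m·cos(α) / (fl·ρ)` (mass g, pennation α, fibre length cm,
  ρ = 1.06 g cm⁻³) and maximal force `F = PCSA · σ` with
  σ = 25 N cm⁻²; forces applied as equal-force strands or as a
  tension-only frictionless wrapped path whose emitted nodal forces sum
  to zero force and moment.
* **Bite statics** — a determinate rigid-body balance whose unknowns
  mirror the FE constraint scheme (vertical bite force; balancing-side
  TMJ fixed in 3 directions, working side in 2), used as an independent
  cross-check of the FE bite reactions.
* **FE solver** — 4-node constant-strain tetrahedra,
  `K_e = V·BᵀDB` assembled vectorised into a sparse symmetric matrix,
  constraints by elimination, sparse Cholesky factorisation,
  reactions as `K u − f`; verified by patch, rigid-mode, closed-form
  and convergence tests.
* **Strain post-processing** — per-element principal strains
  (ε₁ most tensile, ε₃ most compressive, in microstrain), |ε₁:ε₃|
  dominance ratio, sutured-vs-fused absolute/relative difference
  fields, 1 mm² virtual strain gauges at near-suture (IFS/SGS analog)
  and far-field (PB analog) sites, per-bone surface summaries, and
  legacy-ASCII VTK export for ParaView.

## Worked example

```r
library(suturefe)

report <- run_experiment(out_dir = "results_run")
print(report)
#> <run_report> suturefe 0.1.0
#>   incisor_bilateral: statics bite 31.024 N; FE bite sutured 31.024 N, fused 31.024 N
#>     suture strain amplification (sutured): 62.26x
#>   molar_unilateral: statics bite 37.094 N; FE bite sutured 37.094 N, fused 37.094 N
#>     suture strain amplification (sutured): 72.15x
```

Reading the numbers: for each bite scenario the rigid-body statics
prediction and the FE bite reaction agree to all printed digits (the
constraint scheme makes the bite reaction statically determinate — the
5% tolerance in the test suite is generous), and the mean first
principal strain inside suture elements is ~60–70× the mean in bone
within 1 mm of a suture: compliant sutures concentrate strain locally.
The gauge table shows the other half of the story — fusing the sutures
collapses the near-suture gauge readings by orders of magnitude while
the far-field parietal gauge barely moves:

```r
tidy(report)
#> # A tibble: 12 × 9
#>    load_case         variant site      n_nodes  area  e1_mean    e1_sd  e3_mean
#>  1 incisor_bilateral sutured gauge_ifs       5     1 36331.   18642.   -46439.
#>  2 incisor_bilateral sutured gauge_sgs       5     1 19308.    5499.   -14787.
#>  3 incisor_bilateral sutured gauge_pb        4     1    11.4      4.77     -7.60
#>  4 incisor_bilateral fused   gauge_ifs       5     1   238.      13.1    -316.
#>  5 incisor_bilateral fused   gauge_sgs       5     1   323.      38.5    -356.
#>  6 incisor_bilateral fused   gauge_pb        4     1     9.49     3.88     -6.41
#>  ...
```

`run_experiment()` writes, per load case, sutured and fused VTK files
(tissue, ε₁, ε₃, dominance and difference fields as cell data;
displacements and nodal strains as point data) plus `summary.csv`,
`summary_bones.csv`, `gauges.csv` and a deterministic `report.json`.
Individual stages are exposed as ordinary functions —
`build_phantom()`, `default_material_table()` / `apply_variant()`,
`compute_pcsa()`, `solve_unilateral_bite()`, `fe_solve()`,
`principal_field()`, `virtual_gauge()`, `export_vtk()` — and return
tibbles or tidy-able objects throughout. A thin CLI wrapper lives at
`inst/cli/suturefe.R`.

The methods vignette (`vignettes/suture-mechanics.Rmd`) documents the
phantom's design, the material and muscle models, the solver's
numerical choices and the limits of what a green test run establishes.

## Acceptance script

`scripts/acceptance.R` re-runs the complete default experiment from
scratch against the installed package — phantom generation, both load
cases, both material variants, statics cross-check and strain
post-processing — and writes its JSON result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
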