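# qualnet

Executable modelling of cell signalling with **qualitative networks** — the
multi-level generalisation of Boolean networks — plus the in silico screening
pipeline built on top of them: stable-state analysis, mutation and drug
screens across genetic backgrounds, and scoring of model predictions against
experiment tables.

The motivating biology is tumour immune surveillance in the skin: epidermal
Langerhans cells (LCs) detect melanomas and migrate to lymph nodes to prime
T cells, and melanoma-derived TNF-α — produced by an autocrine positive
feedback loop — is the switch that dislodges them. The package ships a
synthetic reduced melanoma–LC model that exhibits this bistable switch and
demonstrates every stage of the pipeline; the engine itself is general and
reads/writes BMA-style model JSON, so any qualitative network can be analysed.

## The model class

A qualitative network has nodes with integer levels in finite ranges
`[min, max]` and signed edges. Each node chases a **target function** of its
regulators; by default

```
T(X) = avg(pos) - avg(neg)
```

with regulator levels rescaled between ranges by
`(y - a)(b' - a')/(b - a) + a'`. Updates are **synchronous** and move each
node one level toward its target per tick, so every trajectory reaches a
**fixed point** or a **loop**; distinct attractors from distinct initial
states constitute a **bifurcation** (multistability). Target evaluation uses
exact rational arithmetic throughout — stability is decided by exact
comparison, never by floating-point tolerance.

Beyond simulation and exhaustive attractor enumeration (the brute-force
oracle for small state spaces), `qn_stable_bounds()` bounds the stable
states of large networks by monotone interval refinement: a sound per-node
box containing every attractor state, with a uniqueness proof when the box
collapses to a point, corner simulation to exhibit bistability otherwise,
and midpoint reporting for loops/bifurcations. Mutations (`qn_knockout()`,
`qn_overexpress()`), drugs (`qn_drug()`) and genetic backgrounds
(`qn_background()`) are all target-function overrides; `qn_screen()` crosses
them (singly or pairwise), computes behaviour readouts and the tumour growth
score (proliferation − apoptosis), and `qn_optimal_pairs()` selects drug
combinations that minimise growth without enhancing LC residency.

## Worked example

A minimal autocrine positive feedback loop is bistable — exhaustive
enumeration finds exactly the off and on states:

```r
library(qualnet)
qn_attractors(qn_motif("tnf_autocrine"))
#> 2 attractor(s) over 81 states (2 fixed point(s), 0 loop(s)) - bifurcation
#> Fixed-point attractor:
#>       TNF      TNFR        TF Residency
#>         0         0         0         2
#> Fixed-point attractor:
#>       TNF      TNFR        TF Residency
#>         2         2         2         0
```

The loop off/on states carry the residency proxy high/low: when the ligand
is produced, the resident cell leaves.

The bundled synthetic melanoma–LC model scales this up:

```r
m <- qn_melanoma_lc()
m$network
#> Qualitative network 'synthetic melanoma-LC model': 44 nodes, 50 edges
#>   ranges: [0,2] [0,3] [0,4]
#>   behaviour nodes: Proliferation, Apoptosis, Residency_LC, Survival_LC, Proliferation_LC

b <- qn_stable_bounds(qn_apply(m$network, m$backgrounds$braf_cdkn2a_pten_mitf_high))
attr(b, "proven_unique")
#> [1] FALSE
qn_reported_level(b, c("TNF", "Residency_LC", "Proliferation", "Apoptosis"))
#>           TNF  Residency_LC Proliferation     Apoptosis
#>             1             2             2             0
```

In this BRAF^V600E CDKN2A^−/− PTEN^−/− MITF-high background the analysis
cannot prove a unique stable state: the TNF loop is bistable, and the
reported TNF level 1 and residency 2 are midpoints of the off/on limits
(`qn_corner_attractors(...)` exhibits the two fixed points, with TNF at 0
and 2). Proliferation 2 with apoptosis 0 gives the baseline growth score +2.

Scoring the bundled experiment table and screening drug pairs:

```r
qn_score_experiments(m$network, m$experiments)
#> Model validation: 17/17 measurements correct (100.0%)

sc <- qn_screen(m$network, m$backgrounds["braf_cdkn2a_pten_mitf_high"],
                unname(m$drugs),
                readouts = c("Residency_LC", "Proliferation", "Apoptosis"),
                pairwise = TRUE)
attr(qn_optimal_pairs(sc, "Residency_LC"), "optimal")
#>   perturbation_1 perturbation_2 tumor_growth_score residency_ok
#> 1    abemaciclib    idasanutlin                 -2         TRUE
#> 2      BMS345541   capivasertib                 -2         TRUE
#> 3      BMS345541     copanlisib                 -2         TRUE
#> 4      HLM006474    idasanutlin                 -2         TRUE
```

Four combinations reach the minimal growth score −2 without enhancing LC
residency: MDM2 inhibition (p53-driven apoptosis) paired with a cell-cycle
block, or IKK inhibition paired with a PI3K/AKT inhibitor (collapsing both
survival arms). MAPK-inhibitor pairs reach the same score but are filtered
out because silencing the TNF loop retains LCs in the skin.

## Command line

A thin wrapper over the same functions is installed at
`system.file("cli", "qnet", package = "qualnet")`:

```sh
qnet simulate --model model_dir --init 0,0,0,2 --out-dir out/
qnet stable   --model model.json --out-dir out/
qnet screen   --model model_dir --backgrounds bg.csv --drugs drugs.csv \
              --pairwise --readouts Residency_LC,Proliferation,Apoptosis --out-dir out/
qnet validate --model model_dir --backgrounds bg.csv --drugs drugs.csv \
              --experiments exp.csv --out-dir out/
qnet generate --motif tnf_autocrine --out-dir out/
qnet convert  --model model_dir --to bma --out-dir out/
```

Exit codes: 0 success, 1 usage/input error, 2 internal failure. Outputs are
deterministic for identical inputs and include a `manifest.json`.

## File formats

- **BMA-style model JSON** (`qn_read_bma()` / `qn_write_bma()`):
  `Model.Variables` with `Id`/`Name`/`RangeFrom`/`RangeTo`/`Formula`,
  `Model.Relationships` with `FromVariable`/`ToVariable`/`Type`; `Layout`
  blocks are preserved opaquely.
- **Tabular models**: `nodes.csv` (`name,min,max,kind`), `edges.csv`
  (`source,target,sign`), `functions.csv` (`node,expression`).
- **Screen inputs**: `backgrounds.csv` (`background,node,level`),
  `drugs.csv` (`drug,class,node,override`), `experiments.csv`
  (`id,background,perturbations,readout,expectation_kind,expectation_value`).

See `vignettes/qualitative-networks.Rmd` for the full account of the
semantics, the soundness argument for the stability bounds, and the design
decisions.
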