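---
title: "Carbon footprint accounting for computational workloads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon footprint accounting for computational workloads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greencompute)
```

## The model

Running a computational job draws electricity, and producing that
electricity emits greenhouse gases. greencompute estimates both with a
two-factor model. The energy a job needs is

$$E \;=\; t \times \left(\sum_i n_{c,i} P_{c,i} u_{c,i} + n_m P_m\right)
\times \mathrm{PUE} \times 0.001 \quad [\mathrm{kWh}],$$

where $t$ is the running time in hours, $n_c$ cores each draw $P_c$
watts at a usage factor $u_c \in [0,1]$, $n_m$ GB of allocated memory
draw $P_m$ W/GB, and PUE (power usage effectiveness) is the facility's
overhead ratio — a PUE of 1.67 means cooling, lighting and power
conversion add 67% on top of what the servers themselves draw. The 0.001
converts Wh to kWh. The carbon footprint is then

$$C \;=\; E \times \mathrm{CI} \quad [\mathrm{kgCO_2e}],$$

with CI the carbon intensity of the electricity grid in kgCO2e/kWh.
Both relations are linear in every factor, which the test suite checks
as exact properties rather than numerical approximations.

Three modelling assumptions matter:

* **Memory is charged on allocation, not use.** Provided memory is
  mobilised, its power draw depends on the amount reserved. This is why
  over-allocation wastes energy (see below), and why the memory term is
  charged once per job regardless of how many cores share it — the sum
  over processor allocations multiplies core power only.
* **Cores are assumed fully used** ($u_c = 1$) unless stated otherwise,
  which slightly overestimates energy for I/O-bound work. The factor is
  configurable per allocation, and the model applies it uniformly to
  CPUs and GPUs.
* **Heterogeneous jobs** (CPU + GPU) are a single task whose processor
  power terms sum inside the parenthesis; the model is agnostic to
  processor kind.

Out of scope by design: idle power, dynamic voltage scaling,
per-process attribution on shared nodes, time-of-day grid variation,
and embodied (manufacturing) carbon.

## Constants and reference tables

All constants live in a versioned YAML file bundled with the package
(`use_reference_data()` substitutes an edited copy):

| constant | value | unit | meaning |
|---|---|---|---|
| `memory_power_per_gb` | 0.3725 | W/GB | memory power density |
| `default_core_power` | 12 | W | per-core draw when hardware is unreported |
| `default_usage_factor` | 1 | — | cores assumed fully used |
| `car_emission_factor` | 0.175 | kgCO2e/km | average European car |
| `tree_month_sequestration` | 0.917 | kgCO2e | one mature tree, one month |

Carbon intensities range over two orders of magnitude between grids
(0.012 in Switzerland to 0.88 in Australia, global average 0.475), and
PUE from 1.11 (Google Cloud) to the 1.67 global average — so *where* a
job runs can matter more than *how* it is written.

A note on the sequestration constant: it is stored as the conventional
rounded 0.917. Some published tree-month figures only reproduce with an
unrounded value near $11/12$ kgCO2e; the YAML therefore also carries
`tree_month_sequestration_unrounded`, but the package computes with the
printed constant and documents the off-by-one tree-month this causes on
multi-tonne footprints rather than silently "fixing" it. Car-kilometre
equivalents reproduce exactly with 0.175 and are preferred for golden
comparisons.

## A worked estimate

A phylogenomics study that consumed 300,000 CPU core-hours, modelled at
the database-average 12 W/core with 8 GB of memory in an average
facility on the average grid:

```{r}
fp <- run_estimate("300,000 h", cores = 1, power_per_core = 12,
                   memory_gb = 8, runtime_kind = "core-hours",
                   quiet = TRUE)
fp
```

Aggregated core-hour totals are modelled as one core running for the
whole core-hour duration (`runtime_kind = "core-hours"` enforces a
single allocation with `cores = 1`), with memory charged over the full
span. This convention reproduces published large-scale footprints from
their printed core-hour totals to within 0.01%.

## The benchmark catalog

`load_catalog()` ships 44 tool-by-experiment benchmark rows across
genome scaffolding and assembly, metagenomics, phylogenetics, RNA-seq,
GWAS and eQTL mapping, and molecular simulation/docking, each carrying
the runtime, memory, printed footprint, contextual equivalents and —
where stated — a scaling law (`linear:reads`, `linear:variants`).
Design choices:

* Rows whose hardware is fully stated in the primary record
  (`hardware_provenance = "primary"`) are recomputed by
  `reproduce_catalog()` and must land within the 0.5% rounding envelope
  of their printed values; rows whose hardware lives only in
  supplementary records ship with empty hardware fields users may fill
  in, and report `reproducible = FALSE` rather than erroring.
* Footprints published as ranges are stored as min/max pairs and
  excluded from reproduction and from the relative-increase rebuild.
* `rebuild_increase_columns()` recomputes each group's
  "+X% vs the greenest tool" column from the printed footprints. The
  published percentages were derived from unrounded internal values, so
  a rebuild from rounded inputs can disagree (severely so where tiny
  footprints were printed with one significant figure); such rows are
  flagged in `matches_printed`, never silently accepted.

## Scenario analyses

**Memory over-allocation.** Reserving $x$ extra multiples of the
required memory (allocated $=(1+x)\times$ required) inflates the
footprint by exactly $100 \cdot f \cdot x$ percent, where $f$ is the
job's memory energy fraction $n_m P_m / (\sum n_c P_c u_c + n_m P_m)$.
A 5-fold over-allocation therefore costs +30% for an assembler whose
memory draws 6% of its energy, but +187% for an aligner at a 37.4%
memory share. The "extra multiples" reading of $x$ (not "allocated
$= x\times$ required") is the one consistent with both figures. The
shortcut is proved equivalent to rerunning the full model with the
inflated allocation.

**Parallelization.** `parallelization_tradeoff()` takes measured
runtimes at several core counts and reports footprint, speedup and
footprint change versus the baseline. With perfect scaling and no
memory the footprint is flat (core-hours are conserved); any sublinear
speedup makes parallel runs dirtier, while a large memory term pulls
the other way because memory is amortised over a shorter wall time.
Cores are assumed independently allocated and fully used; series with
no single-core observation use the smallest core count present as
baseline, with a warning.

**CPU vs GPU.** At equal footprint,
$t_{cpu}/t_{gpu} = (P_{gpu}+m)/(P_{cpu}+m)$ with $m$ the memory power
term charged on both sides. The default ignores memory (the simple
power-draw-ratio approximation): a 300 W GPU must beat a 120 W
16-core CPU by 2.5x to break even. Memory-aware mode is opt-in and
monotonically relaxes the requirement toward 1 as memory grows.

**Location.** Because $C = e \cdot \mathrm{PUE} \cdot \mathrm{CI}$
with $e$ facility-independent, moving a job only rescales by the
PUE × CI product: `compare_locations()` needs no task detail beyond
one baseline footprint, and its percent reductions are invariant to
the baseline's absolute scale. A PUE-only move from 1.67 to 1.11 saves
34%; combining an efficient facility with a clean grid (UK cloud vs
Australian local) saves 81%.

## Scaling laws

Footprints are normalised per unit of work (`per_unit_footprint()`,
with explicit scaled units like "million variants" to keep factors of
$10^6$ out of user code) and extrapolated across input sizes with
`extrapolate_footprint()` under declared laws: linear in reads or
variants for most tools, and power laws elsewhere — e.g. mixed-model
GWAS time grows as $O(N^{1.5})$ in sample size, so quartering the
cohort divides the footprint by 8. Only stated laws are modelled; the
package does not infer complexity from code. `fit_scaling_exponent()`
(ordinary least squares on log–log scale) exists to *verify* exponents
on series, not to discover them.

## The synthetic generator

`generate_tasks()` draws task/facility descriptors with every field
inside configured bounds spanning the catalog's observed ranges:
runtimes 0.002–400,000 h, memory 0.05–262 GB and CI 0.012–0.88
(log-uniform, since they span several orders of magnitude), core counts
1–64, per-core power 8–20 W and PUE 1.1–1.7 (uniform), usage fixed at
1. Generation is deterministic given the seed (Mersenne-Twister) and
restores the caller's RNG state. `generate_scaling_series()` adds
multiplicative log-normal noise — footprints are positive and span
decades, so noise is relative, never additive.

What the generator emulates is the *descriptor* of a job, not the job:
synthetic tasks exercise the arithmetic, the catalog round-trip and the
estimator-recovery properties, but field values are sampled
independently, whereas real workloads correlate (long runtimes go with
big memory). Passing tests therefore demonstrate correctness of the
accounting, not realism of any particular workload mix.

## Numerical choices

* Full floating point everywhere; rounding exists only in the display
  layer (`render_report()`'s table format: two significant figures
  below 1 kg, two decimals below 100, integers above 1,000; integers
  for car-km and tree-months above 10; half-up rounding to match
  conventional reporting). CSV/JSON outputs are never rounded.
* Equality properties (formula-transcription agreement, over-allocation
  shortcut vs full model) are asserted at 1e-12 relative on footprints.
  Percentage *differences* inherit subtraction round-off of order
  $\varepsilon / (f x)$, so they are compared with a small absolute
  slack instead.
* Zero-duration jobs have zero energy and a memory fraction defined as
  0; a memory fraction with all power terms zero is an error, not NaN.
* Problem sizes in the checks — 1,000 random tasks for the oracle
  equivalence, 15–50 points per scaling series, the 44-row catalog —
  keep the whole suite in seconds while leaving the properties sharp.

## Limitations

Estimates are orders of magnitude, not meter readings: TDP-based core
power ignores frequency scaling, the usage factor is rarely measured,
memory power varies by generation, and published benchmarks seldom
report full hardware. Real analyses also rerun tools many times during
tuning, so single-run footprints are lower bounds in practice. For
decisions, the relative comparisons (between tools, facilities, memory
policies) are far more robust than any absolute number.
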