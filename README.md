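# greencompute

Carbon footprint accounting for computational workloads, with a focus
on bioinformatics. Large-scale analyses — biobank GWAS, phylogenomic
inference, genome assembly, molecular simulation — consume enough
electricity that their greenhouse-gas emissions are worth measuring and
minimising, yet few researchers know what a job "costs" in kgCO2e.
greencompute turns the resource figures every scheduler already reports
(runtime, cores, memory) into an emission estimate and into the
decision analyses that actually reduce it: choosing software versions,
memory allocations, core counts, processors and data-centre locations.

## The model

A job's energy draw is

    E [kWh] = t × (Σ nc·Pc·uc + nm·Pm) × PUE × 0.001

with `t` the running time (h), `nc` cores drawing `Pc` W each at usage
factor `uc`, `nm` GB of allocated memory drawing `Pm = 0.3725` W/GB,
and PUE the data-centre overhead (global average 1.67). Its carbon
footprint is

    C [kgCO2e] = E × CI

where CI is the grid's carbon intensity in kgCO2e/kWh (global average
0.475; 0.012 in Switzerland, 0.88 in Australia). Footprints are
contextualised as km driven in an average European car (0.175
kgCO2e/km) and months of carbon sequestration by a mature tree (0.917
kgCO2e/month).

On top of the model the package provides:

* **Reference tables** (`gc_constants()`, `get_carbon_intensity()`,
  `get_pue()`, `processor_catalog()`) in a user-overridable YAML file.
* **A benchmark catalog** (`load_catalog()`) of 44 published
  bioinformatic workload benchmarks with printed footprints,
  reproduction of the hardware-complete rows (`reproduce_catalog()`)
  and rebuilding of the increase-vs-greenest-tool column.
* **Scaling laws** (`per_unit_footprint()`, `extrapolate_footprint()`)
  to normalise per million reads/variants/Gb and extrapolate across
  input sizes.
* **Scenario analyses**: `memory_overallocation_curve()`,
  `parallelization_tradeoff()`, `gpu_cpu_breakeven()`,
  `compare_locations()`.
* **A synthetic task generator** (`generate_tasks()`,
  `generate_scaling_series()`) with known ground truth for testing.
* **A CLI** (`gc_cli()`; thin wrapper in `inst/cli/greencompute.R`)
  with subcommands `estimate`, `memory-sweep`, `parallel-sweep`,
  `breakeven`, `compare-locations`, `catalog`, `synthesize`.

## Worked example

A phylogenomic study that consumed 300,000 CPU core-hours. No hardware
was published, so we use the database-average 12 W/core, 8 GB of
memory, and global-average PUE and CI:

```r
library(greencompute)
fp <- run_estimate("300,000 h", cores = 1, power_per_core = 12,
                   memory_gb = 8, runtime_kind = "core-hours",
                   quiet = TRUE)
fp
#> Carbon footprint: 3,565 kgCO2e
#>   energy: 7505 kWh (compute 6012, memory 1493; memory share 19.9%)
#>   context: PUE 1.67, CI 0.475 kgCO2e/kWh
#>   equivalents: 3,888 tree-months (324 tree-years), 20,371 car-km
```

That single analysis emitted as much as driving a car 20,371 km — or
what 324 trees sequester in a year. Where the job runs matters nearly
as much as what it is: rescaling a 470 kg footprint (a 100-trait
biobank GWAS) by PUE × CI products alone,

```r
compare_locations(470, facility_context(),
                  data.frame(label = c("australia-local", "uk-google-cloud"),
                             pue = c(1.67, 1.11), ci = c(0.88, 0.253)))
#>             label  pue    ci  kg_co2e change_vs_baseline_pct change_vs_worst_pct
#> 1 australia-local 1.67 0.880 870.7368               85.26316             0.00000
#> 2 uk-google-cloud 1.11 0.253 166.3916              -64.59754           -80.89072
```

— running in an efficient UK cloud facility instead of an average
Australian data centre cuts the footprint by 81%. Other one-liners:
`gpu_cpu_breakeven(120, 300)` says a 300 W GPU must run 2.5× faster
than a 120 W CPU to break even, and
`memory_overallocation_curve(0.06, 5)` shows a 5-fold memory
over-allocation adds 30% to a job whose memory draws 6% of its energy.

The same estimate from a shell:

```sh
Rscript inst/cli/greencompute.R estimate \
  --runtime "300000 h" --runtime-kind core-hours \
  --cores 1 --power-per-core 12 --memory 8
```

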