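Package: greencompute
Title: Carbon Footprint Accounting for Computational Workloads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the energy use and greenhouse-gas emissions of
    computational jobs from their resource consumption (running time,
    processing cores, memory, data-centre efficiency, and the carbon
    intensity of the local electricity grid). Ships reference tables of
    carbon intensities, power usage effectiveness values and processor
    power draws, a benchmark catalog of bioinformatic workloads, scaling
    laws for extrapolating footprints across input sizes, and decision
    analyses for memory over-allocation, parallelization, CPU-versus-GPU
    trade-offs and data-centre location.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
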