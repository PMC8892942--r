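# Shared fixtures: random model inputs for property-style tests.

random_task_inputs <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(
      t = exp(runif(1, log(1e-3), log(1e5))),
      nc = sample(1:64, 1),
      pc = runif(1, 1, 300),
      uc = runif(1),
      nm = exp(runif(1, log(0.01), log(500))),
      pm = 0.3725,
      pue = runif(1, 1, 2),
      ci = exp(runif(1, log(0.01), log(1)))
    )
  })
}

task_from_params <- function(p) {
  list(
    resources = task_resources(
      p$t, processor_allocation(p$nc, p$pc, usage = p$uc),
      memory_allocation(p$nm, power_per_gb = p$pm)),
    facility = facility_context(pue = p$pue, ci = p$ci)
  )
}

# Literal transcription of the energy/carbon formulas, kept independent
# of the package internals, as the oracle for equivalence tests.
oracle_kg <- function(p) {
  p$t * (p$nc * p$pc * p$uc + p$nm * p$pm) * p$pue * 0.001 * p$ci
}

scaffold_groups <- function() {
  list(
    long = data.frame(tool = c("SSPACE", "SOAPdenovo2", "SGA"),
                      kg_co2e = c(0.0010, 0.0015, 0.029), size = 2.4),
    short = data.frame(tool = c("SSPACE", "SOAPdenovo2", "SGA"),
                       kg_co2e = c(0.0027, 0.0036, 0.13), size = 22.7)
  )
}
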