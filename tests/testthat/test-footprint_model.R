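test_that("energy model reproduces hand-computed cases", {
  # 1 h on one 100 W core, no memory, ideal facility: 0.1 kWh
  unit <- compute_energy(
    task_resources(1, processor_allocation(1, 100)),
    facility_context(pue = 1, ci = 1))
  expect_equal(unit$total_kwh, 0.1)
  expect_equal(unit$memory_kwh, 0)

  # 300,000 core-hours at 12 W/core with 8 GB, PUE 1.67
  big <- compute_energy(
    task_resources("300,000 h", processor_allocation(1, 12),
                   memory_allocation(8), duration_kind = "core-hours"),
    facility_context())
  expect_equal(big$total_kwh, 7504.98, tolerance = 1e-6)

  # zero duration: no energy, fraction defined as 0
  zero <- compute_energy(
    task_resources(0, processor_allocation(1, 12), memory_allocation(8)),
    facility_context())
  expect_equal(zero$total_kwh, 0)
  expect_equal(zero$memory_fraction, 0)

  expect_equal(big$total_kwh, big$compute_kwh + big$memory_kwh)
})

test_that("footprints of the two large phylogenetics analyses match the printed values", {
  fac <- facility_context()  # PUE 1.67, CI 0.475
  fp1 <- compute_footprint(
    task_resources("300,000 h", processor_allocation(1, 12),
                   memory_allocation(8), duration_kind = "core-hours"), fac)
  expect_equal(fp1$kg_co2e, 3564.87, tolerance = 1e-5)
  expect_equal(round(fp1$kg_co2e), 3565)
  expect_equal(round(fp1$equivalents$car_km), 20371)

  fp2 <- compute_footprint(
    task_resources("367,920 h", processor_allocation(1, 12),
                   memory_allocation(8), duration_kind = "core-hours"), fac)
  expect_equal(fp2$kg_co2e, 4371.95, tolerance = 1e-5)
  expect_equal(round(fp2$equivalents$car_km), 24983)

  # zero carbon intensity nullifies the footprint but not the energy
  fp0 <- compute_footprint(
    task_resources(10, processor_allocation(4, 12), memory_allocation(16)),
    facility_context(pue = 1.5, ci = 0))
  expect_equal(fp0$kg_co2e, 0)
  expect_gt(fp0$energy$total_kwh, 0)
})

test_that("memory energy fraction depends only on the power terms", {
  expect_equal(memory_energy_fraction(
    task_resources(1, processor_allocation(1, 63), memory_allocation(0))), 0)
  # 63 W compute vs a 37 W memory term: f = 0.37
  expect_equal(memory_energy_fraction(
    task_resources(1, processor_allocation(1, 63),
                   memory_allocation(37, power_per_gb = 1))), 0.37)
  # 16 cores x 7.5 W + 100 GB x 0.3725 W/GB
  res <- task_resources(5, processor_allocation(16, 7.5), memory_allocation(100))
  expect_equal(memory_energy_fraction(res), 37.25 / 157.25)

  # invariant under duration (and by construction PUE/CI never enter)
  res2 <- task_resources(5000, processor_allocation(16, 7.5), memory_allocation(100))
  expect_equal(memory_energy_fraction(res2), memory_energy_fraction(res))
  # matches the full energy breakdown's fraction at any facility
  eb <- compute_energy(res, facility_context(pue = 1.9, ci = 0.88))
  expect_equal(eb$memory_fraction, memory_energy_fraction(res))

  expect_error(memory_energy_fraction(
    task_resources(1, processor_allocation(1, 5, usage = 0), memory_allocation(0))),
    "undefined", class = "greencompute_validation_error")
})

test_that("energy and carbon are linear in duration, PUE and CI", {
  for (p in random_task_inputs(25, seed = 11)) {
    base <- task_from_params(p)
    kg <- compute_footprint(base$resources, base$facility)$kg_co2e

    p2 <- p; p2$t <- 2 * p$t
    t2 <- task_from_params(p2)
    expect_equal(compute_footprint(t2$resources, t2$facility)$kg_co2e, 2 * kg)

    # doubling PUE doubles energy (cap at physical lower bound not hit here)
    p3 <- p; p3$pue <- 2 * p$pue
    t3 <- task_from_params(p3)
    expect_equal(compute_energy(t3$resources, t3$facility)$total_kwh,
                 2 * compute_energy(base$resources, base$facility)$total_kwh)

    p4 <- p; p4$ci <- 2 * p$ci
    t4 <- task_from_params(p4)
    expect_equal(compute_footprint(t4$resources, t4$facility)$kg_co2e, 2 * kg)
  }
})

test_that("processor allocations are additive and memory is charged once", {
  fac <- facility_context(pue = 1.4, ci = 0.3)
  cpu <- processor_allocation(8, 10, label = "cpu")
  gpu <- processor_allocation(1, 300, usage = 0.8, label = "gpu")
  both <- compute_energy(task_resources(6, list(cpu, gpu), memory_allocation(32)), fac)
  only_cpu <- compute_energy(task_resources(6, cpu, memory_allocation(32)), fac)
  only_gpu <- compute_energy(task_resources(6, gpu, memory_allocation(0)), fac)
  expect_equal(both$total_kwh, only_cpu$total_kwh + only_gpu$total_kwh)
  # memory appears exactly once in the combined task
  expect_equal(both$memory_kwh, only_cpu$memory_kwh)
})

test_that("modular implementation agrees with a literal formula transcription", {
  params <- random_task_inputs(1000, seed = 101)
  for (p in params) {
    tk <- task_from_params(p)
    got <- compute_footprint(tk$resources, tk$facility)$kg_co2e
    want <- oracle_kg(p)
    expect_lt(abs(got - want) / max(want, .Machine$double.xmin), 1e-12)
  }
})

test_that("unreported memory is excluded and flagged", {
  fp <- compute_footprint(
    task_resources(75, processor_allocation(16, 10),
                   memory_allocation(0, known = FALSE)),
    facility_context())
  expect_true(fp$memory_excluded)
  expect_equal(fp$energy$memory_kwh, 0)
  fp2 <- compute_footprint(
    task_resources(75, processor_allocation(16, 10), memory_allocation(8)),
    facility_context())
  expect_false(fp2$memory_excluded)
})

test_that("input contracts are enforced", {
  expect_error(processor_allocation(0), class = "greencompute_validation_error")
  expect_error(processor_allocation(1, -5), class = "greencompute_validation_error")
  expect_error(processor_allocation(1, 12, usage = 1.2),
               class = "greencompute_validation_error")
  expect_error(memory_allocation(-1), class = "greencompute_validation_error")
  expect_error(task_resources(-1, processor_allocation(1, 12)),
               class = "greencompute_validation_error")
  expect_error(facility_context(pue = 0.8), class = "greencompute_validation_error")
  expect_error(facility_context(ci = -0.1), class = "greencompute_validation_error")
  # core-hour durations model aggregated totals on a single core
  expect_error(task_resources(100, processor_allocation(2, 12),
                              duration_kind = "core-hours"),
               "core-hour", class = "greencompute_validation_error")
})

test_that("contextual equivalents use the car and tree constants", {
  eq <- contextualize(3564.87)
  expect_equal(eq$car_km, 3564.87 / 0.175)
  expect_equal(round(eq$car_km), 20371)
  expect_equal(eq$tree_months, 3564.87 / 0.917)
  expect_equal(eq$tree_years, eq$tree_months / 12)
  eq0 <- contextualize(0)
  expect_equal(unlist(eq0), c(tree_months = 0, tree_years = 0, car_km = 0))
  expect_error(contextualize(-1), class = "greencompute_validation_error")
  eq2 <- contextualize(4371.95)
  expect_equal(round(eq2$car_km), 24983)
})
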