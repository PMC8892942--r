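# Reference tables for greencompute.
# Users may supply an edited copy via use_reference_data() or the CLI
# flag --reference-data. Values are kgCO2e, kWh, W and W/GB as noted.
schema_version: 1
constants:
  memory_power_per_gb: 0.3725      # W per GB of memory allocated
  kwh_conversion: 0.001            # Wh -> kWh
  car_emission_factor: 0.175       # kgCO2e per km, average European passenger car
  tree_month_sequestration: 0.917  # kgCO2e sequestered by one mature tree per month
  # Alternative sequestration constant (11/12 kgCO2e); some published
  # tree-month figures reproduce only with this unrounded value.
  tree_month_sequestration_unrounded: 0.916666666666667
  default_core_power: 12           # W per CPU core when hardware is unreported
  default_usage_factor: 1          # cores assumed fully used
carbon_intensity:                  # kgCO2e per kWh of electricity produced
  global: 0.475
  australia: 0.88
  united-states: 0.453
  united-kingdom: 0.253
  switzerland: 0.012
carbon_intensity_aliases:
  world: global
  uk: united-kingdom
  gb: united-kingdom
  us: united-states
  usa: united-states
pue:                               # total facility power / IT power, >= 1
  global-average: 1.67
  google-cloud: 1.11
  azure: 1.125
  aws: 1.2
pue_aliases:
  default: global-average
  global: global-average
  gcp: google-cloud
  microsoft-azure: azure
  amazon-web-services: aws
processors:
  - name: xeon-e5-2683
    kind: cpu
    core_count: 16
    total_power: 120
    provenance: curated
  - name: tesla-v100
    kind: gpu
    core_count: 1
    total_power: 300
    provenance: curated
  # Vendor TDP figures; excluded from reproduction tests.
  - name: tesla-t4
    kind: gpu
    core_count: 1
    total_power: 70
    provenance: vendor
  - name: tesla-p100
    kind: gpu
    core_count: 1
    total_power: 250
    provenance: vendor
  - name: xeon-gold-6142
    kind: cpu
    core_count: 16
    total_power: 150
    provenance: vendor
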