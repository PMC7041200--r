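# Default model inputs: annual preventive dental intervention vs usual care.
# Probabilities of new caries are on the observed 2-year scale and are
# converted to annual transition probabilities at model-build time.
# Costs are AUD (2018) from the public fee schedule.
settings:
  horizon: 10
  cycle_length: 1
  discount_cost: 0.05
  discount_qaly: 0.0
  cohort_size: 500
  wtp: 50000
  fraction_plaque_calculus: 0.50
  fraction_ohi_diet: 0.25
  fraction_sealant: 1.0
  treated_return: seek_mix
  rate_conversion: rate
  include_initial_lesions: false
parameters:
  - {name: p_caries, arm: comparison, base: 0.80, low: 0.74, high: 0.85, dist: beta, scale: probability, source: study data}
  - {name: p_caries, arm: intervention, base: 0.71, low: 0.65, high: 0.78, dist: beta, scale: probability, source: study data}
  - {name: p_new_caries_2y, arm: comparison, base: 0.637, low: 0.357, high: 0.714, dist: beta, scale: probability, source: study data}
  - {name: p_new_caries_2y, arm: intervention, base: 0.479, low: 0.316, high: 0.545, dist: beta, scale: probability, source: study data}
  - {name: p_seek_treatment, arm: comparison, base: 0.68, low: 0.63, high: 0.73, dist: triangular, scale: probability, source: national survey}
  - {name: p_seek_treatment, arm: intervention, base: 0.90, low: 0.68, high: 1.00, dist: triangular, scale: probability, source: study data}
  - {name: p_restoration, arm: shared, base: 0.40, rel_bounds: 0.15, dist: fixed, scale: probability, source: study data}
  - {name: p_extraction, arm: shared, base: 0.06, rel_bounds: 0.15, dist: fixed, scale: probability, source: study data}
  - {name: p_pulp_therapy, arm: shared, base: 0.04, rel_bounds: 0.15, dist: fixed, scale: probability, source: study data}
  - {name: cost_examination, arm: shared, base: 53, low: 48, high: 78, dist: fixed, scale: currency, source: fee schedule}
  - {name: cost_restoration, arm: shared, base: 145, low: 117, high: 229, dist: gamma, scale: currency, source: fee schedule}
  - {name: cost_extraction, arm: shared, base: 195, low: 84, high: 442, dist: fixed, scale: currency, source: fee schedule}
  - {name: cost_pulp_therapy, arm: shared, base: 77, low: 31, high: 538, dist: fixed, scale: currency, source: fee schedule}
  - {name: cost_fissure_sealant, arm: shared, base: 47, low: 42, high: 47, dist: fixed, scale: currency, source: fee schedule}
  - {name: cost_radiography, arm: shared, base: 38, low: 31, high: 95, dist: fixed, scale: currency, source: fee schedule}
  - {name: cost_varnish, arm: shared, base: 30, dist: fixed, scale: currency, source: fee schedule}
  - {name: cost_plaque_removal, arm: shared, base: 55, dist: fixed, scale: currency, source: fee schedule}
  - {name: cost_calculus_removal, arm: shared, base: 91, low: 82, high: 91, dist: fixed, scale: currency, source: fee schedule}
  - {name: cost_oral_hygiene, arm: shared, base: 50, dist: fixed, scale: currency, source: fee schedule}
  - {name: cost_dietary_advice, arm: shared, base: 37, dist: fixed, scale: currency, source: fee schedule}
  - {name: utility_caries, arm: shared, base: 0.87, low: 0.80, high: 0.90, dist: fixed, scale: utility, source: CHU-9D}
  - {name: utility_healthy, arm: shared, base: 1.00, low: 0.95, high: 1.00, dist: fixed, scale: utility, source: CHU-9D}
scenarios:
  equal_initial_caries:
    - {name: p_caries, arm: intervention, value: 0.80}
  zero_initial_caries:
    - {name: p_caries, arm: intervention, value: 0.0}
    - {name: p_caries, arm: comparison, value: 0.0}
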