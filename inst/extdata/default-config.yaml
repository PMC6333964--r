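# Default configuration for the timegeo pipeline. Values here are the
# package defaults; a user config overrides individual keys.

# hours per canonical unit (30-day months, 365-day years)
unit_factors:
  second: 0.0002777777777777778
  minute: 0.016666666666666666
  hour: 1.0
  day: 24.0
  week: 168.0
  month: 720.0
  year: 8760.0

# keywords accepted after a numeral in an explicit statement
explicit_keywords:
  - time point
  - time-point
  - timepoint
  - time series
  - stage
  - developmental stage
  - phase

# qualitative temporal phrases (qualifier x head)
approximate_qualifiers: [early, middle, late, terminal]
approximate_heads: [stage, phase, age, time point]

# rule-i vocabulary and token window
sample_vocab: [sample, samples, patient, patients, subject, subjects]
window: 2

# tolerances
progression_tol: 1.0e-6
dedupe_tol: 1.0e-9

output_format: jsonl
log_level: info
seed: 42
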