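# Fixture provenance

- `life_table_us_synthetic.csv` — synthetic sex-specific annual death
  probabilities, ages 50–110. Constructed as per-sex Gompertz hazards
  calibrated to published US annual death probabilities at ages 55 and 85
  (male q55 = 0.0077, q85 = 0.096; female q55 = 0.0046, q85 = 0.071), with
  q forced to 1 at the terminal age 110. Implied life expectancy at 55:
  24.4 y (male), 28.0 y (female). This is a constructed approximation to a
  CDC-style life table, not a transcription of one.
- `sex_proportions_us_synthetic.csv` — census-like proportion female by
  base age (55–75 in 5-year steps). Constructed round approximations, not a
  transcription.
- AD incidence coefficients (annual incidence 0.00117 at age 60, doubling
  every ln(2)/0.126 ≈ 5.5 years above 60, halving per 5 years below 60)
  live in the default configuration; see `incidence_model()`.
- `base_case_config.yaml` — the fully enumerated base-case run
  configuration, written by `write_config(default_config(), ...)`.
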