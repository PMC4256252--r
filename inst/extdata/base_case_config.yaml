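base_age: 55
population_size: 1000000
n_trials: 1000
trial_size: 1000
seed: 1
strategy: screen_and_treat
risk_set: original
count_censored: yes
benefit_model: masked
incidence:
  lambda60: 0.00117
  doubling_time: 5.501168099682
  sub60_halving_interval: 5.0
progression:
  initial_severity:
    mild: 0.6
    moderate: 0.4
    severe: 0.0
  transitions:
    mild:
      mild: 0.614614614615
      moderate: 0.322322322322
      severe: 0.042042042042
      dead: 0.021021021021
    moderate:
      mild: 0.0
      moderate: 0.590386624869
      severe: 0.354231974922
      dead: 0.055381400209
    severe:
      mild: 0.0
      moderate: 0.0
      severe: 0.847
      dead: 0.153
  nh_entry:
    mild: 0.038
    moderate: 0.11
    severe: 0.259
  ad_utilities:
    mild:
      community: 0.37
      nursing_home: 0.52
    moderate:
      community: 0.18
      nursing_home: 0.21
    severe:
      community: 0.02
      nursing_home: 0.0
  no_ad_utilities:
    age_55_64: 0.872
    age_65_74: 0.836
    age_75_84: 0.809
    age_85_plus: 0.775
  discount_rate: 0.03
treatment:
  rrr_slope: 0.03
  rrr_ceiling: 0.5
  harm_prob: 0.001
  harm_magnitude: 0.06
  discontinuation_rate: 0.05
screening:
  sensitivity: 0.65
  specificity: 0.95
  horizon_years: 20.0
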