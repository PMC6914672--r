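# Default needsim configuration: week-long case study of a working adult.
# Times are decimal clock hours; durations are decimal elapsed hours.
simulation:
  days: 7
  warmup_hours: 8
  start_weekday: Sunday
  start_time: "16:00"
needs:
  lambda: 0.2
  epsilon: 1.0e-9
  eta_travel: 0.0
  eta_income: 0.1
activities:
  sleep:
    start_mu: 22
    start_sigma: 0.5
    end_mu: 8
    end_sigma: 2.5
  eat_breakfast:
    start_mu: 8.25
    start_sigma: 0
    duration_mu: 0.25
    duration_sigma: 0
  commute_to_work:
    duration_mu: 0.5
    duration_sigma: 0
  work:
    start_mu: 9
    start_sigma: 0
    end_mu: 17
    end_sigma: 0.08
  eat_lunch:
    start_mu: 12
    start_sigma: 0.25
    duration_mu: 0.5
    duration_sigma: 0.17
  commute_from_work:
    duration_mu: 1
    duration_sigma: 0
  eat_dinner:
    start_mu: 19
    start_sigma: 0.17
    duration_mu: 0.75
    duration_sigma: 0.08
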