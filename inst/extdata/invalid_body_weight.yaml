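label: model_1
tasks:
- farming
seasons:
- annual
baselines:
  ingestion:
    concentration: 0.000219
    intake_rate: 100.0
    exposure_factor: 0.16
    body_weight: -80.0
  dermal:
    concentration: 219.0
    conversion_factor: 1.0e-06
    adherence_factor: 0.07
    absorption_fraction: 0.0002722
    surface_area: 3527.0
    exposure_frequency: 250.0
    exposure_duration: 1.0
    event_frequency: 1.0
    body_weight: 80.0
    averaging_time: 365.0
schedules:
- task: farming
  season: annual
  exposure_factor: 0.16
  exposure_frequency: 250.0
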