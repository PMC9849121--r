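label: model_7
tasks:
- transplanting
- harvesting
- watering
seasons:
- spring
- summer
- fall
- winter
baselines:
  ingestion:
    concentration: 0.000219
    intake_rate: 100.0
    exposure_factor: 0.16
    body_weight: 80.0
  dermal:
    concentration: 219.0
    conversion_factor: 1.0e-06
    adherence_factor: 0.07
    absorption_fraction: 0.000272185993762
    surface_area: 3527.0
    exposure_frequency: 250.0
    exposure_duration: 1.0
    event_frequency: 1.0
    body_weight: 80.0
    averaging_time: 365.0
schedules:
- task: transplanting
  season: spring
  exposure_factor: 0.053333333333333
  exposure_frequency: 60.119047619047628
- task: harvesting
  season: spring
  exposure_factor: 0.066849315068493
  exposure_frequency: 60.119047619047628
- task: watering
  season: spring
  exposure_factor: 0.004018264840183
  exposure_frequency: 36.111111111111121
- task: transplanting
  season: summer
  exposure_factor: 0.053333333333333
  exposure_frequency: 60.119047619047628
- task: harvesting
  season: summer
  exposure_factor: 0.066849315068493
  exposure_frequency: 60.119047619047628
- task: watering
  season: summer
  exposure_factor: 0.004018264840183
  exposure_frequency: 36.111111111111121
- task: harvesting
  season: fall
  exposure_factor: 0.066849315068493
  exposure_frequency: 36.111111111111121
- task: watering
  season: fall
  exposure_factor: 0.004018264840183
  exposure_frequency: 36.111111111111121
modifiers:
- factor: natural
  target: intake_rate
  action: multiply
  value: 1.5
  tasks:
  - transplanting
  seasons:
  - spring
- factor: natural
  target: intake_rate
  action: multiply
  value: 1.497267759562841
  tasks:
  - harvesting
  seasons:
  - spring
- factor: natural
  target: intake_rate
  action: multiply
  value: 0.299090909090909
  tasks:
  - watering
  seasons:
  - spring
- factor: natural
  target: intake_rate
  action: multiply
  value: 2.0
  tasks:
  - transplanting
  seasons:
  - summer
- factor: natural
  target: intake_rate
  action: multiply
  value: 1.994535519125683
  tasks:
  - harvesting
  seasons:
  - summer
- factor: natural
  target: intake_rate
  action: multiply
  value: 2.645454545454546
  tasks:
  - watering
  seasons:
  - summer
- factor: natural
  target: adherence_factor
  action: override
  value: 0.2
  seasons:
  - spring
  - fall
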