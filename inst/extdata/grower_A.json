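{
  "label": "grower_A",
  "tasks": [
    "transplanting",
    "harvesting",
    "watering"
  ],
  "seasons": [
    "spring",
    "summer",
    "fall",
    "winter"
  ],
  "baselines": {
    "ingestion": {
      "concentration": 0.000219,
      "intake_rate": 100,
      "exposure_factor": 0.16,
      "body_weight": 80
    },
    "dermal": {
      "concentration": 219,
      "conversion_factor": 1e-06,
      "adherence_factor": 0.07,
      "absorption_fraction": 0.000272185993762404,
      "surface_area": 3527,
      "exposure_frequency": 250,
      "exposure_duration": 1,
      "event_frequency": 1,
      "body_weight": 80,
      "averaging_time": 365
    }
  },
  "schedules": [
    {
      "task": "transplanting",
      "season": "spring",
      "exposure_factor": 0.0533333333333333,
      "exposure_frequency": 60.1190476190476
    },
    {
      "task": "harvesting",
      "season": "spring",
      "exposure_factor": 0.0668493150684931,
      "exposure_frequency": 60.1190476190476
    },
    {
      "task": "watering",
      "season": "spring",
      "exposure_factor": 0.00401826484018265,
      "exposure_frequency": 36.1111111111111
    },
    {
      "task": "transplanting",
      "season": "summer",
      "exposure_factor": 0.0533333333333333,
      "exposure_frequency": 60.1190476190476
    },
    {
      "task": "harvesting",
      "season": "summer",
      "exposure_factor": 0.0668493150684931,
      "exposure_frequency": 60.1190476190476
    },
    {
      "task": "watering",
      "season": "summer",
      "exposure_factor": 0.00401826484018265,
      "exposure_frequency": 36.1111111111111
    },
    {
      "task": "harvesting",
      "season": "fall",
      "exposure_factor": 0.0668493150684931,
      "exposure_frequency": 36.1111111111111
    },
    {
      "task": "watering",
      "season": "fall",
      "exposure_factor": 0.00401826484018265,
      "exposure_frequency": 36.1111111111111
    }
  ],
  "modifiers": [
    {
      "factor": "natural",
      "target": "intake_rate",
      "action": "multiply",
      "value": 1.5,
      "tasks": [
        "transplanting"
      ],
      "seasons": [
        "spring"
      ]
    },
    {
      "factor": "natural",
      "target": "intake_rate",
      "action": "multiply",
      "value": 1.49726775956284,
      "tasks": [
        "harvesting"
      ],
      "seasons": [
        "spring"
      ]
    },
    {
      "factor": "natural",
      "target": "intake_rate",
      "action": "multiply",
      "value": 0.299090909090909,
      "tasks": [
        "watering"
      ],
      "seasons": [
        "spring"
      ]
    },
    {
      "factor": "natural",
      "target": "intake_rate",
      "action": "multiply",
      "value": 2,
      "tasks": [
        "transplanting"
      ],
      "seasons": [
        "summer"
      ]
    },
    {
      "factor": "natural",
      "target": "intake_rate",
      "action": "multiply",
      "value": 1.99453551912568,
      "tasks": [
        "harvesting"
      ],
      "seasons": [
        "summer"
      ]
    },
    {
      "factor": "natural",
      "target": "intake_rate",
      "action": "multiply",
      "value": 2.64545454545455,
      "tasks": [
        "watering"
      ],
      "seasons": [
        "summer"
      ]
    },
    {
      "factor": "natural",
      "target": "adherence_factor",
      "action": "override",
      "value": 0.2,
      "seasons": [
        "spring",
        "fall"
      ]
    }
  ],
  "receptor": {
    "label": "grower_A",
    "body_weight": 64,
    "age_band": "20s",
    "sex": "female",
    "modifiers": [
      {
        "factor": "biological",
        "target": "intake_rate",
        "action": "multiply",
        "value": 0.887671232876712,
        "tasks": [
          "transplanting"
        ],
        "seasons": [
          "spring"
        ]
      },
      {
        "factor": "biological",
        "target": "intake_rate",
        "action": "multiply",
        "value": 0.884671532846715,
        "tasks": [
          "harvesting"
        ],
        "seasons": [
          "spring"
        ]
      },
      {
        "factor": "biological",
        "target": "intake_rate",
        "action": "multiply",
        "value": 0.885106382978723,
        "tasks": [
          "watering"
        ],
        "seasons": [
          "spring"
        ]
      },
      {
        "factor": "biological",
        "target": "intake_rate",
        "action": "multiply",
        "value": 0.887671232876712,
        "tasks": [
          "transplanting"
        ],
        "seasons": [
          "summer"
        ]
      },
      {
        "factor": "biological",
        "target": "intake_rate",
        "action": "multiply",
        "value": 1.41808219178082,
        "tasks": [
          "harvesting"
        ],
        "seasons": [
          "summer"
        ]
      },
      {
        "factor": "biological",
        "target": "intake_rate",
        "action": "multiply",
        "value": 0.0332646048109966,
        "tasks": [
          "watering"
        ],
        "seasons": [
          "summer"
        ]
      },
      {
        "factor": "biological",
        "target": "intake_rate",
        "action": "multiply",
        "value": 0.883060109289617,
        "tasks": [
          "harvesting"
        ],
        "seasons": [
          "fall"
        ]
      },
      {
        "factor": "biological",
        "target": "intake_rate",
        "action": "multiply",
        "value": 0.88,
        "tasks": [
          "watering"
        ],
        "seasons": [
          "fall"
        ]
      },
      {
        "factor": "biological",
        "target": "surface_area",
        "action": "multiply",
        "value": 0.0126600660066007,
        "tasks": [
          "transplanting"
        ],
        "seasons": [
          "spring"
        ]
      },
      {
        "factor": "biological",
        "target": "surface_area",
        "action": "multiply",
        "value": 0.014970297029703,
        "tasks": [
          "harvesting"
        ],
        "seasons": [
          "spring"
        ]
      },
      {
        "factor": "biological",
        "target": "surface_area",
        "action": "multiply",
        "value": 0.0149846153846154,
        "tasks": [
          "watering"
        ],
        "seasons": [
          "spring"
        ]
      },
      {
        "factor": "biological",
        "target": "surface_area",
        "action": "multiply",
        "value": 0.0306270627062706,
        "tasks": [
          "transplanting"
        ],
        "seasons": [
          "summer"
        ]
      },
      {
        "factor": "biological",
        "target": "surface_area",
        "action": "multiply",
        "value": 0.0306270627062706,
        "tasks": [
          "harvesting"
        ],
        "seasons": [
          "summer"
        ]
      },
      {
        "factor": "biological",
        "target": "surface_area",
        "action": "multiply",
        "value": 0.0305054945054945,
        "tasks": [
          "watering"
        ],
        "seasons": [
          "summer"
        ]
      },
      {
        "factor": "biological",
        "target": "surface_area",
        "action": "multiply",
        "value": 0.00941538461538462,
        "tasks": [
          "harvesting"
        ],
        "seasons": [
          "fall"
        ]
      },
      {
        "factor": "biological",
        "target": "surface_area",
        "action": "multiply",
        "value": 0.00941538461538462,
        "tasks": [
          "watering"
        ],
        "seasons": [
          "fall"
        ]
      }
    ]
  }
}
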