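{
  "format": "pulsetree-network",
  "units": {
    "length": "cm",
    "radius": "cm",
    "stiffness": "dyn/cm2"
  },
  "root_id": 1,
  "segments": [
    {
      "id": 1,
      "name": "MPA",
      "parent": null,
      "length_cm": 3.73176332590115,
      "radius_cm": 0.746352665180231,
      "extralobar": true,
      "stiffness_dyn_cm2": null
    },
    {
      "id": 2,
      "name": "LPA",
      "parent": 1,
      "length_cm": 2.94809302746191,
      "radius_cm": 0.589618605492382,
      "extralobar": true,
      "stiffness_dyn_cm2": null
    },
    {
      "id": 3,
      "name": "RPA",
      "parent": 1,
      "length_cm": 2.94809302746191,
      "radius_cm": 0.589618605492382,
      "extralobar": true,
      "stiffness_dyn_cm2": null
    },
    {
      "id": 4,
      "name": "L4",
      "parent": 2,
      "length_cm": 2.32899349169491,
      "radius_cm": 0.465798698338982,
      "extralobar": false,
      "stiffness_dyn_cm2": null
    },
    {
      "id": 5,
      "name": "L5",
      "parent": 2,
      "length_cm": 2.32899349169491,
      "radius_cm": 0.465798698338982,
      "extralobar": false,
      "stiffness_dyn_cm2": null
    },
    {
      "id": 6,
      "name": "R6",
      "parent": 3,
      "length_cm": 2.32899349169491,
      "radius_cm": 0.465798698338982,
      "extralobar": false,
      "stiffness_dyn_cm2": null
    },
    {
      "id": 7,
      "name": "R7",
      "parent": 3,
      "length_cm": 2.32899349169491,
      "radius_cm": 0.465798698338982,
      "extralobar": false,
      "stiffness_dyn_cm2": null
    }
  ]
}
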