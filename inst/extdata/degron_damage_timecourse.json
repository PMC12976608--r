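{
  "schema_version": 1,
  "protocol": {
    "samples": ["culture_1", "culture_2", "culture_3", "culture_4", "culture_5", "culture_6", "culture_7", "culture_8"],
    "operations": [
      {
        "name": "Add auxin",
        "duration": "0.5",
        "wait_after": "240",
        "color": "#1B9E77"
      },
      {
        "name": "Add HU",
        "duration": "0.5",
        "wait_after": "29.5",
        "color": "#E7298A"
      },
      {
        "name": "Harvest extract @ 30",
        "duration": "6",
        "wait_after": "24",
        "color": "#D95F02"
      },
      {
        "name": "Harvest extract @ 60",
        "duration": "6",
        "wait_after": "54",
        "color": "#D95F02"
      },
      {
        "name": "Harvest extract @ 120",
        "duration": "6",
        "wait_after": "114",
        "color": "#D95F02"
      },
      {
        "name": "Harvest extract @ 240",
        "duration": "6",
        "wait_after": "0",
        "color": "#D95F02"
      }
    ],
    "buffer": "1",
    "granularity": "0.25",
    "mode": "automatic",
    "manual_interval": null
  },
  "display": {
    "base_color": null,
    "x_tick": null
  }
}
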