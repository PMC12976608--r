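{
  "schema_version": 1,
  "protocol": {
    "samples": ["culture_01", "culture_02", "culture_03", "culture_04", "culture_05", "culture_06", "culture_07", "culture_08", "culture_09", "culture_10", "culture_11", "culture_12"],
    "operations": [
      {
        "name": "Add 4tU",
        "duration": "1",
        "wait_after": "4",
        "color": "#1B9E77"
      },
      {
        "name": "Harvest @ 5",
        "duration": "3",
        "wait_after": "7",
        "color": "#D95F02"
      },
      {
        "name": "Harvest @ 15",
        "duration": "3",
        "wait_after": "12",
        "color": "#D95F02"
      },
      {
        "name": "Harvest @ 30",
        "duration": "3",
        "wait_after": "27",
        "color": "#D95F02"
      },
      {
        "name": "Harvest @ 60",
        "duration": "3",
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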