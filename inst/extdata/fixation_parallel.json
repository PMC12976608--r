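{
  "schema_version": 1,
  "protocol": {
    "samples": ["coverslip_01", "coverslip_02", "coverslip_03", "coverslip_04", "coverslip_05", "coverslip_06", "coverslip_07", "coverslip_08", "coverslip_09", "coverslip_10", "coverslip_11", "coverslip_12"],
    "operations": [
      {
        "name": "Add drug",
        "duration": "0.5",
        "wait_after": "60",
        "color": "#1B9E77"
      },
      {
        "name": "Wash + start fixation",
        "duration": "5",
        "wait_after": "15",
        "color": "#D95F02"
      },
      {
        "name": "Wash + halt fixation",
        "duration": "5",
        "wait_after": "0",
        "color": "#7570B3"
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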