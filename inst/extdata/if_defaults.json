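{
  "PPC": {
    "kind": "PPC",
    "values": [0.00469, 0.00112, 0.0044],
    "units_note": "h1 in mm inside ln; permittivity difference relative (dimensionless); IF in GF units",
    "provenance": "published-default"
  },
  "SPC": {
    "kind": "SPC",
    "values": [2830, 1000, 1300],
    "units_note": "h1 in mm in the 1/h1 term; permittivity ratio relative (dimensionless); IF in GF units",
    "provenance": "published-default"
  }
}
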