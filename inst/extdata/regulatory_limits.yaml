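# National limits for Cd and As in paddy soil-rice systems, mg/kg.
# mac: maximum allowable concentration in milled rice (GB 2762)
# rsv: soil risk screening value (GB 15618), pH-binned
# riv: soil risk intervention value (GB 15618), pH-binned
- element: Cd
  ph_bin: neutral
  mac: 0.2
  rsv: 0.6
  riv: 3.0
- element: Cd
  ph_bin: alkaline
  mac: 0.2
  rsv: 0.8
  riv: 4.0
- element: As
  ph_bin: neutral
  mac: 0.5
  rsv: 25.0
  riv: 120.0
- element: As
  ph_bin: alkaline
  mac: 0.5
  rsv: 20.0
  riv: 100.0
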