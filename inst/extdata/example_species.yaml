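species:
- id: littorina_littorea
  larval_min_days: 28.0
  larval_max_days: 49.0
  impacts:
    biodiversity: 2
    interactions: 2
    habitat: 3
    trophic: 2
  presence_ports:
  - S02
  - S03
  - S05
  uncertainty_impact: low
- id: mya_arenaria
  larval_min_days: 14.0
  larval_max_days: 21.0
  impacts:
    biodiversity: 2
    interactions: 2
    habitat: 3
    trophic: 2
  presence_ports:
  - S02
  - S03
  uncertainty_impact: low
- id: paralithodes_camtschaticus
  larval_min_days: 61.0
  larval_max_days: 91.0
  impacts:
    biodiversity: 3
    interactions: 3
    habitat: 2
    trophic: 3
  presence_ports:
  - S03
  uncertainty_impact: low
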