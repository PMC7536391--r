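# Example crop-calendar configuration (conventional values, editable).
# Fields: season window in day-of-year, degree-day thresholds in degrees C.
barley:
  season_start: 91
  season_end: 243
  gdd_base: 0
  gdd_ceiling: 25
  edd_threshold: 25
corn:
  season_start: 91
  season_end: 273
  gdd_base: 8
  gdd_ceiling: 32
  edd_threshold: 29
cotton:
  season_start: 91
  season_end: 304
  gdd_base: 10
  gdd_ceiling: 33
  edd_threshold: 32
rice:
  season_start: 91
  season_end: 273
  gdd_base: 8
  gdd_ceiling: 33
  edd_threshold: 32
soybeans:
  season_start: 121
  season_end: 288
  gdd_base: 8
  gdd_ceiling: 30
  edd_threshold: 30
wheat:
  season_start: 60
  season_end: 196
  gdd_base: 0
  gdd_ceiling: 26
  edd_threshold: 26
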