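segments:
- 40.0
- 40.0
- 40.0
- 40.0
- 40.0
- 40.0
- 40.0
- 40.0
feeders:
  'N': 40.0
  E: 120.0
  S: 200.0
  W: 280.0
sensor_offset_cm: 15.0
start_position: 0.0
run_direction: clockwise
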