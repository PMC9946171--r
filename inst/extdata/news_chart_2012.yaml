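# National Early Warning Score, Royal College of Physicians 2012 chart.
# Each parameter partitions its measurement axis into bands; `upper` holds
# the inclusive upper edge of each band (last band unbounded), `points` the
# score for that band, `resolution` the measurement grid the chart assumes
# (values are rounded half-up to it before lookup).
version: news2012
parameters:
  respiratory_rate:
    unit: breaths/min
    resolution: 1
    upper: [8, 11, 20, 24, .inf]
    points: [3, 1, 0, 2, 3]
  spo2:
    unit: percent
    resolution: 1
    upper: [91, 93, 95, .inf]
    points: [3, 2, 1, 0]
  temperature:
    unit: celsius
    resolution: 0.1
    upper: [35.0, 36.0, 38.0, 39.0, .inf]
    points: [3, 1, 0, 1, 2]
  sbp:
    unit: mmHg
    resolution: 1
    upper: [90, 100, 110, 219, .inf]
    points: [3, 2, 1, 0, 3]
  heart_rate:
    unit: bpm
    resolution: 1
    upper: [40, 50, 90, 110, 130, .inf]
    points: [3, 1, 0, 1, 2, 3]
supplemental_oxygen_points: 2
not_alert_points: 3
max_score: 20
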