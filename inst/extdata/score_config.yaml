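# ILLUSTRATIVE SYNTHETIC scoring configuration.
# Band tables and acceptance ranges here are invented for tests and examples;
# they mimic the *shape* of malt-house end-use scoring (points per trait band,
# higher = better for that brewing style) but are not a published table.
# Units: AA 20-deg DU, DP deg-ASBC, FAN ppm, BG ppm, ME/SP/MP/ST percent.
adjunct:
  bands:
    AA:
      - {min: 70, max: .inf, points: 3}
      - {min: 55, max: 70, points: 2}
      - {min: 45, max: 55, points: 1}
    DP:
      - {min: 150, max: .inf, points: 3}
      - {min: 120, max: 150, points: 2}
      - {min: 100, max: 120, points: 1}
    FAN:
      - {min: 230, max: .inf, points: 3}
      - {min: 200, max: 230, points: 2}
      - {min: 170, max: 200, points: 1}
    BG:
      - {min: -.inf, max: 120, points: 3}
      - {min: 120, max: 200, points: 2}
      - {min: 200, max: 280, points: 1}
    ME:
      - {min: 81, max: .inf, points: 3}
      - {min: 79, max: 81, points: 2}
      - {min: 77, max: 79, points: 1}
    SP:
      - {min: 5.6, max: .inf, points: 3}
      - {min: 5.0, max: 5.6, points: 2}
      - {min: 4.4, max: 5.0, points: 1}
    ST:
      - {min: 48, max: .inf, points: 3}
      - {min: 42, max: 48, points: 2}
      - {min: 36, max: 42, points: 1}
  range:
    AA: {min: 60, max: 90}
    FAN: {min: 210, max: 300}
    BG: {min: 0, max: 180}
    ME: {min: 79, max: 100}
    ST: {min: 42, max: 55}
all_malt:
  bands:
    AA:
      - {min: 50, max: .inf, points: 3}
      - {min: 40, max: 50, points: 2}
      - {min: 30, max: 40, points: 1}
    DP:
      - {min: 110, max: .inf, points: 3}
      - {min: 90, max: 110, points: 2}
      - {min: 70, max: 90, points: 1}
    FAN:
      - {min: 160, max: 240, points: 3}
      - {min: 130, max: 160, points: 2}
      - {min: 100, max: 130, points: 1}
    BG:
      - {min: -.inf, max: 140, points: 3}
      - {min: 140, max: 220, points: 2}
      - {min: 220, max: 300, points: 1}
    ME:
      - {min: 80, max: .inf, points: 3}
      - {min: 78, max: 80, points: 2}
      - {min: 76, max: 78, points: 1}
    SP:
      - {min: 4.6, max: 5.8, points: 3}
      - {min: 4.0, max: 4.6, points: 2}
      - {min: 3.4, max: 4.0, points: 1}
    ST:
      - {min: 38, max: 46, points: 3}
      - {min: 32, max: 38, points: 2}
      - {min: 26, max: 32, points: 1}
  range:
    AA: {min: 45, max: 75}
    FAN: {min: 140, max: 230}
    BG: {min: 0, max: 200}
    ME: {min: 78, max: 100}
    ST: {min: 36, max: 48}
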