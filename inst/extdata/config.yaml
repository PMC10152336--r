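radius_m: 300.0
geo_poll_interval_min: 2
step_sync_interval_min: 60
geo_window:
- 480
- 1200
geo_daily_cap: 3
geo_min_gap_min: 240
morning_window:
- 480
- 540
midday_window:
- 690
- 750
evening_window:
- 960
- 1080
bct_subset_k: 4
strata_bounds:
- 2000
- 6000
score_map:
  '-1': 1
  '0': 5
  '1': 10
step_goal:
- 7000
- 8000
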