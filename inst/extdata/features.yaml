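features:
- name: thermal_time_veg
  kind: degree_days
  window:
    anchor: sowing
    mode: to_anchor
    end_anchor: petal_fall
- name: thermal_time_pod
  kind: degree_days
  window:
    anchor: petal_fall
    mode: to_anchor
    end_anchor: harvest
- name: thermal_time_total
  kind: degree_days
  window:
    anchor: sowing
    mode: to_anchor
    end_anchor: harvest
- name: cum_radiation_veg
  kind: stat
  variable: radiation
  statistic: sum
  window:
    anchor: sowing
    mode: to_anchor
    end_anchor: petal_fall
- name: avg_radiation_veg
  kind: stat
  variable: radiation
  statistic: mean
  window:
    anchor: sowing
    mode: to_anchor
    end_anchor: petal_fall
- name: cum_radiation_pod
  kind: stat
  variable: radiation
  statistic: sum
  window:
    anchor: petal_fall
    mode: to_anchor
    end_anchor: harvest
- name: avg_radiation_pod
  kind: stat
  variable: radiation
  statistic: mean
  window:
    anchor: petal_fall
    mode: to_anchor
    end_anchor: harvest
- name: avg_tmin_veg
  kind: stat
  variable: tmin
  statistic: mean
  window:
    anchor: sowing
    mode: to_anchor
    end_anchor: petal_fall
- name: avg_tmax_veg
  kind: stat
  variable: tmax
  statistic: mean
  window:
    anchor: sowing
    mode: to_anchor
    end_anchor: petal_fall
- name: avg_tmean_veg
  kind: stat
  variable: tmean
  statistic: mean
  window:
    anchor: sowing
    mode: to_anchor
    end_anchor: petal_fall
- name: avg_tmin_pod
  kind: stat
  variable: tmin
  statistic: mean
  window:
    anchor: petal_fall
    mode: to_anchor
    end_anchor: harvest
- name: avg_tmax_pod
  kind: stat
  variable: tmax
  statistic: mean
  window:
    anchor: petal_fall
    mode: to_anchor
    end_anchor: harvest
- name: avg_tmean_pod
  kind: stat
  variable: tmean
  statistic: mean
  window:
    anchor: petal_fall
    mode: to_anchor
    end_anchor: harvest
- name: avg_tmin_total
  kind: stat
  variable: tmin
  statistic: mean
  window:
    anchor: sowing
    mode: to_anchor
    end_anchor: harvest
- name: avg_vp_veg
  kind: stat
  variable: vapour_pressure
  statistic: mean
  window:
    anchor: sowing
    mode: to_anchor
    end_anchor: petal_fall
- name: avg_vp_pod
  kind: stat
  variable: vapour_pressure
  statistic: mean
  window:
    anchor: petal_fall
    mode: to_anchor
    end_anchor: harvest
- name: stress275_veg
  kind: stress
  threshold: 27.5
  window:
    anchor: sowing
    mode: to_anchor
    end_anchor: petal_fall
- name: stress30_veg
  kind: stress
  threshold: 30.0
  window:
    anchor: sowing
    mode: to_anchor
    end_anchor: petal_fall
- name: stress275_pod
  kind: stress
  threshold: 27.5
  window:
    anchor: petal_fall
    mode: to_anchor
    end_anchor: harvest
- name: stress30_pod
  kind: stress
  threshold: 30.0
  window:
    anchor: petal_fall
    mode: to_anchor
    end_anchor: harvest
- name: stress30_5d_pf
  kind: stress
  threshold: 30.0
  window:
    anchor: petal_fall
    mode: fixed_days
    'n': 5.0
    direction: after
- name: stress30_15d_pf
  kind: stress
  threshold: 30.0
  window:
    anchor: petal_fall
    mode: fixed_days
    'n': 15.0
    direction: after
- name: stress275_15d_pf
  kind: stress
  threshold: 27.5
  window:
    anchor: petal_fall
    mode: fixed_days
    'n': 15.0
    direction: after
- name: avg_radiation_7d_sow
  kind: stat
  variable: radiation
  statistic: mean
  window:
    anchor: sowing
    mode: fixed_days
    'n': 7.0
    direction: after
- name: avg_radiation_28d_sow
  kind: stat
  variable: radiation
  statistic: mean
  window:
    anchor: sowing
    mode: fixed_days
    'n': 28.0
    direction: after
- name: avg_tmax_14d_sow
  kind: stat
  variable: tmax
  statistic: mean
  window:
    anchor: sowing
    mode: fixed_days
    'n': 14.0
    direction: after
- name: avg_tmin_14d_sow
  kind: stat
  variable: tmin
  statistic: mean
  window:
    anchor: sowing
    mode: fixed_days
    'n': 14.0
    direction: after
- name: avg_tmax_28d_sow
  kind: stat
  variable: tmax
  statistic: mean
  window:
    anchor: sowing
    mode: fixed_days
    'n': 28.0
    direction: after
- name: avg_tmin_28d_sow
  kind: stat
  variable: tmin
  statistic: mean
  window:
    anchor: sowing
    mode: fixed_days
    'n': 28.0
    direction: after
- name: avg_vp_28d_sow
  kind: stat
  variable: vapour_pressure
  statistic: mean
  window:
    anchor: sowing
    mode: fixed_days
    'n': 28.0
    direction: after
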