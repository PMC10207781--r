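# Default run configuration: 2019 accounting of a breast-radiology
# screening service and the three waiting-list strategies compared in the
# packaged analysis. Printed accounting/QALY figures that do not decompose
# from the component model are carried as overrides (use_printed_overrides).

tumor_model:
  doubling_time_days: 168.5        # calibrated: Td -> Tp sojourn ~ 4.6 y
  cell_density_per_cm3: 1.0e+09
  detection_cells: 1.0e+07         # Td, ~3 mm
  palpability_cells: 1.0e+10       # Tp, ~25-30 mm
  days_per_month: 30.4375

costs:
  staff_daily_per_team: 608.28     # EUR, 5 working hours
  goods_services_daily: 128.59
  overheads_daily: 92.65
  equipment_daily: 30.82
  staff_annual: 856825.94
  goods_services_annual: 225288.23
  overheads_annual: 162317.13
  equipment_annual: 54000.00
  working_hours_per_day: 5
  working_days_3y: 728.37          # back-solved from the 3-year totals

tariffs:
  paying_exam_fee: 87.00
  ticket_fee: 36.15
  paying_fraction: 0.35

strategies:
  - name: current
    teams_day: 2
    teams_afternoon: 0
    mammographs: 2
    ultrasounds: 3
    reporting_stations: 3
    exams_per_day: 40
    waiting_months: 32
    patients_3y: 30000
    overrides:
      daily_cost: 1468.61
      cost_3y: 1069687.68
  - name: 22-month
    teams_day: 3
    teams_afternoon: 0
    mammographs: 3
    ultrasounds: 4
    reporting_stations: 3
    exams_per_day: 60
    waiting_months: 22
    patients_3y: 45000
    overrides:
      daily_cost: 2715.99
      cost_3y: 1978238.64
  - name: 16-month
    teams_day: 2
    teams_afternoon: 2
    mammographs: 2
    ultrasounds: 3
    reporting_stations: 3
    exams_per_day: 80
    waiting_months: 16
    patients_3y: 60000
    overrides:
      daily_cost: 2906.40
      daily_revenue: 7936.05
      cost_3y: 2116927.08

qol:
  non_met_first_year: 0.696
  non_met_subsequent: 0.779
  metastatic_all_years: 0.685

survival_table: seer_life_expectancy_synthetic.csv

# Incident patients per strategy and stratum over the 3-year horizon.
incident:
  - {strategy: current, stratum: metastatic, incident: 12.8}
  - {strategy: current, stratum: non_metastatic, incident: 25.9}
  - {strategy: 22-month, stratum: metastatic, incident: 14.9}
  - {strategy: 22-month, stratum: non_metastatic, incident: 43.2}
  - {strategy: 16-month, stratum: metastatic, incident: 11.2}
  - {strategy: 16-month, stratum: non_metastatic, incident: 66.3}

# Published stratum QALYs (used when use_printed_overrides is true; the
# unrounded inputs behind them are not recoverable).
qaly_printed:
  - {strategy: current, stratum: metastatic, qaly: 10.3}
  - {strategy: current, stratum: non_metastatic, qaly: 50.6}
  - {strategy: 22-month, stratum: metastatic, qaly: 12.0}
  - {strategy: 22-month, stratum: non_metastatic, qaly: 84.4}
  - {strategy: 16-month, stratum: metastatic, qaly: 9.0}
  - {strategy: 16-month, stratum: non_metastatic, qaly: 129.4}

# Observed stage-wise metastasis probabilities under the reference
# (32-month) strategy; calibration column for the Poisson seeding model.
observed_stage_probabilities:
  - {stage: T1A, point: 0.00}
  - {stage: T1B, point: 0.03}
  - {stage: T1C, point: 0.20}
  - {stage: T2, point: 0.59}

cohort:
  "n": 242
  stage_freqs: {T1A: 20, T1B: 65, T1C: 95, T2: 59, T3: 3}
  node_freqs: {N0: 154, N+: 88}
  histology_freqs: {ductal: 189, lobular: 44, tubular: 5, mucinous: 2}
  grade_freqs: {"1": 79, "2": 109, "3": 47}

reference_strategy: current
use_printed_overrides: true
wtp_threshold: null
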