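# 8-week home-training protocol: 5 weekly 30-minute sessions, ~10 minutes
# per exercise per day, one session a day, adaptive staircase from the
# shared starting records (3x3 span of length 3; N = 0) at the slowest rate.
program:
  duration_weeks: 8
  sessions_per_week: 5
  max_training_days_per_week: 5
  session_minutes: 30
  per_exercise_daily_minutes:
    vs_wm: 10
    op_nb: 10
    d_nb: 10
  max_sessions_per_day: 1
thresholds:
  vs_wm: 100
  op_nb: 80
  d_nb: 75
ladders:
  vs_wm:
    rate_steps: [2.0, 1.75, 1.5, 1.25, 1.0]
    base: {grid_rows: 3, grid_cols: 3, sequence_length: 3}
  op_nb:
    rate_steps: [4.5, 4.0, 3.5, 3.0]
    base: {n_back: 0, digit_lo: 1, digit_hi: 9}
  d_nb:
    rate_steps: [4.5, 4.0, 3.5, 3.0]
    base: {n_back: 0}
responder:
  capacity: 5
  p_high: 0.95
  p_floor: 0.05
  slope: 0.35
  miss_rate: 0.02
settings:
  user_mode: true
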