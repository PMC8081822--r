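# Default pipeline configuration: the four top European divisions over
# four baseline seasons, with the closed-door block sizes of 2019/2020.
leagues:
  - league: DE
    matchdays_per_season: 34
    matches_per_matchday: 9
    closed_door_matches: 83
  - league: ES
    matchdays_per_season: 38
    matches_per_matchday: 10
    closed_door_matches: 111
  - league: EN
    matchdays_per_season: 38
    matches_per_matchday: 10
    closed_door_matches: 92
  - league: IT
    matchdays_per_season: 38
    matches_per_matchday: 10
    closed_door_matches: 130
baseline_seasons:
  - "2015/2016"
  - "2016/2017"
  - "2017/2018"
  - "2018/2019"
closed_door_season: "2019/2020"
null_spec:
  n_draws: 1000000
  scheme: overall_stratified
  tie_rule: inclusive_both
  alpha: 0.05
  zero_denominator_share: 0.5
sim_params:
  null_mode: false
  goal_rates: {home: 1.5, away: 1.2}
  shot_rates: {home: 14, away: 11}
  possession_shape: {alpha: 20, beta: 17}
  foul_rates: {home: 12, away: 13}
  yellow_rates: {home: 1.8, away: 2.1}
  red_probs: {home: 0.04, away: 0.06}
  effect: {goals: 1, shots: 1, possession: 1, fouls: 1, yellows: 1, reds: 1}
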