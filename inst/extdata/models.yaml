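# Published prediction models for hoverfly flight-mill performance.
# Conventions: 3-level ordinal factors (condition: thin<medium<fat; size:
# small<moderate<large) enter through orthonormal polynomial contrasts
# (linear, quadratic); baseline morph is summer and baseline direction is
# anti-clockwise; time is trial time normalised to (0,1] and time_log its
# natural log. Links are log unless stated; back-transforming the linear
# predictor yields response-scale group predictions. Mixed-model coefficient
# sets are evaluated as fixed-effect predictors only.
contrast_convention: orthonormal_polynomial
baselines:
  morph: summer
  direction: anti-clockwise
models:
  distance:
    response: total distance flown over the 4 h trial
    units: m
    family: Gamma
    link: log
    n_obs: 141
    pseudo_r2: 0.186
    dispersion: 2.29
    coefficients:
      "(Intercept)": 6.00
      morph_autumn: 0.77
      direction_clockwise: 0.68
      condition_linear: 1.08
      condition_quadratic: -0.22
    se:
      "(Intercept)": 0.29
      morph_autumn: 0.29
      direction_clockwise: 0.26
      condition_linear: 0.27
      condition_quadratic: 0.21
  mean_speed:
    response: flight-time-weighted mean speed over the trial
    units: m/s
    family: Gamma
    link: log
    n_obs: 141
    pseudo_r2: 0.087
    dispersion: 0.242
    coefficients:
      "(Intercept)": -0.53
      direction_clockwise: 0.13
      size_linear: 0.27
      size_quadratic: -0.13
    se:
      "(Intercept)": 0.08
      direction_clockwise: 0.09
      size_linear: 0.12
      size_quadratic: 0.08
  flight_initiation:
    response: mean idle seconds per initiated flight (log-transformed
      Gaussian linear model; predictions back-transform with exp)
    units: s
    family: gaussian_log_response
    link: log
    n_obs: 141
    r2_adj: 0.838
    coefficients:
      "(Intercept)": 7.13
      morph_autumn: -0.50
      condition_linear: -1.51
      condition_quadratic: -0.13
      "morph_autumn:condition_linear": 1.00
      "morph_autumn:condition_quadratic": 0.33
    se:
      "(Intercept)": 0.25
      morph_autumn: 0.29
      condition_linear: 0.49
      condition_quadratic: 0.38
      "morph_autumn:condition_linear": 0.56
      "morph_autumn:condition_quadratic": 0.44
  per_flight_distance:
    response: distance of an individual flight event (fixed effects of a
      Gamma mixed model; random fly intercept not evaluated)
    units: m
    family: Gamma
    link: log
    n_obs: 3607
    pseudo_r2_fixed: 0.248
    dispersion: 0.807
    coefficients:
      "(Intercept)": 1.22
      morph_autumn: 0.80
      condition_linear: 0.89
      condition_quadratic: 0.13
      size_linear: 0.37
      size_quadratic: -0.25
      direction_clockwise: 0.75
      time: 0.49
      time_log: -0.31
      "morph_autumn:time": -0.47
      "condition_linear:time": -1.02
      "condition_quadratic:time": -0.28
    se:
      "(Intercept)": 0.28
      morph_autumn: 0.25
      condition_linear: 0.23
      condition_quadratic: 0.19
      size_linear: 0.30
      size_quadratic: 0.21
      direction_clockwise: 0.22
      time: 0.14
      time_log: 0.01
      "morph_autumn:time": 0.13
      "condition_linear:time": 0.15
      "condition_quadratic:time": 0.11
  transect_speed:
    response: last-second-of-minute sampled flight speed (fixed effects of a
      Gamma mixed model)
    units: m/s
    family: Gamma
    link: log
    n_obs: 5282
    pseudo_r2_fixed: 0.171
    dispersion: 0.119
    coefficients:
      "(Intercept)": -1.30
      morph_autumn: 0.22
      condition_linear: 0.32
      condition_quadratic: -0.11
      size_linear: 0.19
      size_quadratic: -0.11
      direction_clockwise: 0.15
      time: 0.30
      time_log: -0.23
      "morph_autumn:time": -0.34
      "morph_autumn:time_log": 0.07
      "condition_linear:time": -0.34
      "condition_quadratic:time": 0.00
      "condition_linear:time_log": 0.01
      "condition_quadratic:time_log": -0.05
    se:
      "(Intercept)": 0.13
      morph_autumn: 0.12
      condition_linear: 0.12
      condition_quadratic: 0.09
      size_linear: 0.11
      size_quadratic: 0.08
      direction_clockwise: 0.08
      time: 0.10
      time_log: 0.02
      "morph_autumn:time": 0.10
      "morph_autumn:time_log": 0.02
      "condition_linear:time": 0.12
      "condition_quadratic:time": 0.08
      "condition_linear:time_log": 0.02
      "condition_quadratic:time_log": 0.02
  activity:
    response: per-minute probability of flying (fixed effects of a binomial
      mixed model)
    units: proportion
    family: binomial
    link: logit
    n_obs: 33840
    pseudo_r2_fixed: 0.223
    coefficients:
      "(Intercept)": -3.04
      morph_autumn: 0.79
      condition_linear: 2.06
      condition_quadratic: -0.32
      time: -0.62
      time_log: -0.58
      "morph_autumn:condition_linear": -0.75
      "morph_autumn:condition_quadratic": -0.08
      "condition_linear:time_log": 0.23
      "condition_quadratic:time_log": -0.15
    se:
      "(Intercept)": 0.29
      morph_autumn: 0.07
      condition_linear: 0.14
      condition_quadratic: 0.10
      time: 0.12
      time_log: 0.03
      "morph_autumn:condition_linear": 0.13
      "morph_autumn:condition_quadratic": 0.09
      "condition_linear:time_log": 0.04
      "condition_quadratic:time_log": 0.03
# Published morphometric prediction tables (linear-model estimates for 23
# dried specimens). Dry mass is condition + size with no interaction; wing
# length depends on size only. Cell n of 0 marks combinations estimated by
# the model without direct observations.
morphometrics:
  dry_mass:
    units: mg
    cells:
      - {condition: thin,   size: small,    estimate: 3.7,  se: 2.2, n_obs: 0}
      - {condition: thin,   size: moderate, estimate: 5.7,  se: 1.6, n_obs: 3}
      - {condition: thin,   size: large,    estimate: 12.8, se: 2.2, n_obs: 0}
      - {condition: medium, size: small,    estimate: 7.5,  se: 1.1, n_obs: 5}
      - {condition: medium, size: moderate, estimate: 9.5,  se: 1.3, n_obs: 3}
      - {condition: medium, size: large,    estimate: 16.5, se: 1.2, n_obs: 4}
      - {condition: fat,    size: small,    estimate: 11.5, se: 1.6, n_obs: 1}
      - {condition: fat,    size: moderate, estimate: 13.5, se: 1.1, n_obs: 5}
      - {condition: fat,    size: large,    estimate: 20.6, se: 1.4, n_obs: 2}
  wing_length:
    units: mm
    cells:
      - {size: small,    estimate: 4.95, se: 0.10, n_obs: 6}
      - {size: moderate, estimate: 5.45, se: 0.07, n_obs: 11}
      - {size: large,    estimate: 5.84, se: 0.10, n_obs: 6}
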