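allometries:
  pipe_la_pooled:
    label: global pipe LA (pooled PFTs)
    response: LA
    predictor: a_cb
    scope: pooled
    elevation: 2370.0
    slope: 0.94
    cf: 1.065
    'n': 768
    range:
    - 1.0e-05
    - 1.0e+00
    pi:
      form: quadratic
      c0: 0.71655
      c1: 0.0059
      c2: 0.00052
      residual_se: 2.0e-05
  qpipe_la_pooled:
    label: global qPipe LA (pooled PFTs)
    response: LA
    predictor: a_cb_est
    scope: pooled
    elevation: 2742.0
    slope: 0.955
    cf: 1.077
    'n': 768
    range:
    - 1.0e-05
    - 1.0e+00
    pi:
      form: quadratic
      c0: 0.77894
      c1: 0.00622
      c2: 0.00054
      residual_se: 2.0e-05
  qpipe_lm_EC:
    label: global qPipe LM (EC)
    response: LM
    predictor: a_cb_est
    scope: per-pft
    elevation: 854.4
    slope: 1.078
    cf: 1.023
    'n': 221
    range:
    - 1.0e-05
    - 1.0e+00
    pft: EC
    pi:
      form: quadratic
      c0: 0.4892
      c1: 0.01772
      c2: 0.00181
      residual_se: 2.0e-05
  qpipe_lm_DC:
    label: global qPipe LM (DC)
    response: LM
    predictor: a_cb_est
    scope: per-pft
    elevation: 571.4
    slope: 1.172
    cf: 1.059
    'n': 57
    range:
    - 1.0e-05
    - 1.0e+00
    pft: DC
    pi:
      form: ls
      c0: 2.004
      c1: 0.3389
      c2: 57.0
      c3: -5.206
      c4: 62.89
  qpipe_lm_EB:
    label: global qPipe LM (EB)
    response: LM
    predictor: a_cb_est
    scope: per-pft
    elevation: 293.8
    slope: 0.973
    cf: 1.073
    'n': 447
    range:
    - 1.0e-05
    - 1.0e+00
    pft: EB
    pi:
      form: quadratic
      c0: 0.78223
      c1: 0.01286
      c2: 0.00112
      residual_se: 7.0e-05
  qpipe_lm_DB:
    label: global qPipe LM (DB)
    response: LM
    predictor: a_cb_est
    scope: per-pft
    elevation: 180.3
    slope: 1.017
    cf: 1.073
    'n': 227
    range:
    - 1.0e-05
    - 1.0e+00
    pft: DB
    pi:
      form: quadratic
      c0: 0.81205
      c1: 0.01924
      c2: 0.00159
      residual_se: 7.0e-05
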