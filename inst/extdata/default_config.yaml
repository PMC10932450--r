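version: 1
grid:
  lo_nm: 500.0
  hi_nm: 850.0
  step_nm: 0.02
catalog:
  bins:
  - label: Ca_547.89
    element: Ca
    center_nm: 547.889999999999986
    lo_nm: 546.889999999999986
    hi_nm: 548.889999999999986
  - label: Ca_554.52
    element: Ca
    center_nm: 554.519999999999982
    lo_nm: 553.519999999999982
    hi_nm: 555.519999999999982
  - label: Ca_560.01
    element: Ca
    center_nm: 560.009999999999991
    lo_nm: 559.009999999999991
    hi_nm: 561.009999999999991
  - label: Ca_596.05
    element: Ca
    center_nm: 596.049999999999955
    lo_nm: 595.049999999999955
    hi_nm: 597.049999999999955
  - label: Ca_604.21
    element: Ca
    center_nm: 604.210000000000036
    lo_nm: 603.210000000000036
    hi_nm: 605.210000000000036
  - label: Ca_610.08
    element: Ca
    center_nm: 610.080000000000041
    lo_nm: 609.080000000000041
    hi_nm: 611.080000000000041
  - label: Ca_616.66
    element: Ca
    center_nm: 616.659999999999968
    lo_nm: 615.659999999999968
    hi_nm: 617.659999999999968
  - label: Ca_625.88
    element: Ca
    center_nm: 625.879999999999995
    lo_nm: 624.879999999999995
    hi_nm: 626.879999999999995
  - label: Ca_635.58
    element: Ca
    center_nm: 635.580000000000041
    lo_nm: 634.580000000000041
    hi_nm: 636.580000000000041
  - label: Ca_643.38
    element: Ca
    center_nm: 643.379999999999995
    lo_nm: 642.379999999999995
    hi_nm: 644.379999999999995
  - label: Ca_650.80
    element: Ca
    center_nm: 650.799999999999955
    lo_nm: 649.799999999999955
    hi_nm: 651.799999999999955
  - label: K_765.86
    element: K
    center_nm: 765.860000000000014
    lo_nm: 764.860000000000014
    hi_nm: 766.860000000000014
  - label: K_770.76
    element: K
    center_nm: 770.759999999999991
    lo_nm: 769.759999999999991
    hi_nm: 771.759999999999991
  - label: Na_589.14
    element: Na
    center_nm: 589.139999999999986
    lo_nm: 588.139999999999986
    hi_nm: 590.139999999999986
  - label: Na_819.42
    element: Na
    center_nm: 819.419999999999959
    lo_nm: 818.419999999999959
    hi_nm: 820.419999999999959
model:
  classes:
    fibrosis:
      ca:
        median: 4.973
        iqr: 8.369
      k:
        median: 3.339
        iqr: 1.31
      na:
        median: 6.0
        iqr: 1.8
    nerve:
      ca:
        median: 63.640000000000001
        iqr: 15.07
      k:
        median: 1.738
        iqr: 1.652
      na:
        median: 1.5
        iqr: 0.45
    tumor_stroma:
      ca:
        median: 30.039999999999999
        iqr: 40.460000000000001
      k:
        median: 5.669
        iqr: 2.812
      na:
        median: 2.0
        iqr: 0.6
    cell_rich_tumor:
      ca:
        median: 1.974
        iqr: 6.47
      k:
        median: 6.498
        iqr: 1.75
      na:
        median: 6.0
        iqr: 1.8
    healthy_bone_ref:
      ca:
        median: 80.0
        iqr: 24.0
      k:
        median: 1.0
        iqr: 0.3
      na:
        median: 1.0
        iqr: 0.3
    tumor_ref:
      ca:
        median: 2.0
        iqr: 0.6
      k:
        median: 7.0
        iqr: 2.1
      na:
        median: 1.0
        iqr: 0.3
  fwhm_nm: 1.0
  baseline: 0.02
  noise_sd: 2.0e-05
  ref_center_nm: 800.0
  ref_height: 1.0
  trunc_q: 0.995
  gain_meanlog: 0.5
  gain_sdlog: 0.3
counts:
  fibrosis: 254
  nerve: 516
  tumor_stroma: 821
  cell_rich_tumor: 1458
seed: 42
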