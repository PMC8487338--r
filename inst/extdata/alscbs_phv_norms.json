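{
  "version": "italian-normative-study-v1",
  "note": "Adjustment equations and Equivalent Score band tables from the published Italian normative study of the ALS-CBS Phone Version. Sign convention: AS = RS + coefficient * (T(x) - center). Read-only fixture; derived norms are written to user files.",
  "equations": [
    {
      "measure": "total",
      "terms": [
        {"covariate": "age", "transform": "ln_100_minus_x", "coefficient": -2.036709, "center": 3.791907},
        {"covariate": "education", "transform": "ln_x", "coefficient": -2.700291, "center": 2.497723}
      ]
    },
    {
      "measure": "attention",
      "terms": [
        {"covariate": "age", "transform": "x_squared", "coefficient": 0.000159, "center": 3024.637883},
        {"covariate": "education", "transform": "sqrt_x", "coefficient": -0.355773, "center": 3.55473}
      ]
    },
    {
      "measure": "concentration_wm",
      "terms": [
        {"covariate": "age", "transform": "x_cubed", "coefficient": 0.000001, "center": 185105.752089},
        {"covariate": "education", "transform": "ln_x", "coefficient": -0.628171, "center": 2.497723}
      ]
    },
    {
      "measure": "concentration_total",
      "terms": [
        {"covariate": "age", "transform": "x_cubed", "coefficient": 0.000002, "center": 185105.752089},
        {"covariate": "education", "transform": "ln_x", "coefficient": -1.259983, "center": 2.497723}
      ]
    },
    {
      "measure": "tracking_monitoring",
      "terms": [
        {"covariate": "age", "transform": "x_cubed", "coefficient": 0.000001, "center": 185105.752089},
        {"covariate": "education", "transform": "ln_x", "coefficient": -0.86209, "center": 2.497723}
      ]
    },
    {
      "measure": "initiation_retrieval",
      "terms": [
        {"covariate": "age", "transform": "ln_100_minus_x", "coefficient": -0.496252, "center": 3.791907},
        {"covariate": "education", "transform": "sqrt_x", "coefficient": -0.414521, "center": 3.55473}
      ]
    }
  ],
  "bands": [
    {"measure": "total", "oTL": 12.42, "iTL": 13.55, "es_upper": [12.42, 14.07, 15.86, 17.13]},
    {"measure": "attention", "oTL": 1.77, "iTL": 2.85, "es_upper": [1.77, 3.18, 4.01, 4.49]},
    {"measure": "concentration_wm", "oTL": 2.8, "iTL": 3.05, "es_upper": [2.8, 3.47, 3.94, 4.66]},
    {"measure": "concentration_total", "oTL": 2.8, "iTL": 3.98, "es_upper": [2.8, 4.31, 5.42, 6.34]},
    {"measure": "tracking_monitoring", "oTL": 1.88, "iTL": 2.54, "es_upper": [1.88, 2.77, 3.73, 4.59]},
    {"measure": "initiation_retrieval", "oTL": 1.84, "iTL": 2.69, "es_upper": [1.84, 2.81, 3.58, 4.09]}
  ]
}
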