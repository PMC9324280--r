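{
  "schema_version": "1.0",
  "type": "ensemble_model",
  "decision_threshold": 1,
  "provenance": "published NPC/BH linear-SVR ensemble; placeholder z-score parameters (means 0, sds 1)",
  "weights": [0.33508, 0.36677, 0.62281, 0.42553, 0.33341],
  "folds": [
    {
      "feature_ids": [
        "original|shape|SurfaceVolumeRatio",
        "lbp-3D-k|glrlm|LongRunHighGrayLevelEmphasis",
        "original|shape|SurfaceArea",
        "lbp-3D-m2|first-order|Kurtosis",
        "log-sigma-0-4492-mm-3D|first-order|Mean",
        "original|shape|LeastAxisLength",
        "exponential|glcm|SumEntropy",
        "lbp-3D-m1|first-order|Kurtosis",
        "gradient|first-order|Energy",
        "lbp-2D|glcm|DifferenceVariance"
      ],
      "coefficients": [-0.3435, -0.23201, -0.15209, -0.07727, 0.08879, 0.10404, 0.04001, -0.08219, 0.05771, -0.02907],
      "intercept": 0.48176,
      "youden_threshold": 0.5968723886833,
      "zscore": {
        "means": [0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
        "sds": [1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
      }
    },
    {
      "feature_ids": [
        "original|shape|SurfaceVolumeRatio",
        "lbp-3D-k|glrlm|LongRunHighGrayLevelEmphasis",
        "original|shape|SurfaceArea",
        "lbp-3D-m2|first-order|Kurtosis",
        "original|shape|LeastAxisLength",
        "gradient|first-order|Energy",
        "exponential|first-order|Energy",
        "exponential|glrlm|RunVariance",
        "lbp-3D-m2|glrlm|ShortRunHighGrayLevelEmphasis"
      ],
      "coefficients": [-0.41914, -0.23496, -0.12242, -0.16856, 0.11893, 0.01792, -0.05008, -0.04025, 0.00498],
      "intercept": 0.49719,
      "youden_threshold": 0.545300869754887,
      "zscore": {
        "means": [0, 0, 0, 0, 0, 0, 0, 0, 0],
        "sds": [1, 1, 1, 1, 1, 1, 1, 1, 1]
      }
    },
    {
      "feature_ids": [
        "original|shape|SurfaceVolumeRatio",
        "lbp-3D-k|glrlm|LongRunHighGrayLevelEmphasis",
        "original|shape|SurfaceArea",
        "lbp-3D-m2|first-order|Kurtosis",
        "log-sigma-0-4492-mm-3D|first-order|Mean",
        "original|shape|LeastAxisLength",
        "lbp-3D-m1|glcm|ClusterShade"
      ],
      "coefficients": [-0.35446, -0.19496, -0.13933, -0.15919, 0.05899, 0.10616, -0.06451],
      "intercept": 0.49814,
      "youden_threshold": 0.321125222780623,
      "zscore": {
        "means": [0, 0, 0, 0, 0, 0, 0],
        "sds": [1, 1, 1, 1, 1, 1, 1]
      }
    },
    {
      "feature_ids": [
        "original|shape|SurfaceVolumeRatio",
        "lbp-3D-k|glrlm|LongRunHighGrayLevelEmphasis",
        "original|shape|SurfaceArea",
        "lbp-3D-m2|first-order|Kurtosis",
        "log-sigma-0-4492-mm-3D|first-order|Mean",
        "exponential|glcm|SumEntropy",
        "log-sigma-0-4492-mm-3D|first-order|RobustMeanAbsoluteDeviation"
      ],
      "coefficients": [-0.41196, -0.23516, -0.05791, -0.17252, -0.06722, -0.00654, -0.1053],
      "intercept": 0.47659,
      "youden_threshold": 0.470002115009518,
      "zscore": {
        "means": [0, 0, 0, 0, 0, 0, 0],
        "sds": [1, 1, 1, 1, 1, 1, 1]
      }
    },
    {
      "feature_ids": [
        "original|shape|SurfaceVolumeRatio",
        "lbp-3D-k|glrlm|LongRunHighGrayLevelEmphasis",
        "original|shape|SurfaceArea",
        "log-sigma-0-4492-mm-3D|first-order|Mean",
        "exponential|glcm|SumEntropy",
        "lbp-3D-m1|first-order|Kurtosis",
        "exponential|first-order|Energy",
        "exponential|first-order|Variance",
        "original|glrlm|RunEntropy"
      ],
      "coefficients": [-0.35104, -0.1868, -0.10701, 0.15951, 0.1332, -0.14464, 0.02571, -0.1247, 0.05171],
      "intercept": 0.47752,
      "youden_threshold": 0.599862031732701,
      "zscore": {
        "means": [0, 0, 0, 0, 0, 0, 0, 0, 0],
        "sds": [1, 1, 1, 1, 1, 1, 1, 1, 1]
      }
    }
  ]
}
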