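{
  "resource": "per-phase logistic prediction models, fixed published coefficients",
  "version": "1.0",
  "coding": {
    "gender": {"male": 1, "female": 0},
    "flags": {"present": 1, "absent": 0},
    "class": {"ccRCC": 1, "AML.wovf": 0}
  },
  "threshold": 0.5,
  "models": {
    "PCP": {
      "intercept": 5.257,
      "terms": [
        {"term": "gender", "coef": 3.137, "or": 23.028, "ci_lower": 4.892, "ci_upper": 108.408, "p": 0.000},
        {"term": "pseudocapsule", "coef": 2.549, "or": 12.801, "ci_lower": 1.453, "ci_upper": 112.806, "p": 0.022},
        {"term": "angular", "coef": 2.155, "or": 8.628, "ci_lower": 1.956, "ci_upper": 38.059, "p": 0.004},
        {"term": "AVT_PCP_1", "coef": -0.215, "or": 0.806, "ci_lower": 0.720, "ci_upper": 0.903, "p": 0.000}
      ]
    },
    "CMP": {
      "intercept": -35.318,
      "terms": [
        {"term": "gender", "coef": 6.796, "or": 894.054, "ci_lower": 11.272, "ci_upper": 70915.930, "p": 0.002},
        {"term": "cystic", "coef": 3.361, "or": 28.816, "ci_lower": 1.803, "ci_upper": 460.581, "p": 0.017},
        {"term": "RER_CMP_2", "coef": 0.185, "or": 1.203, "ci_lower": 1.075, "ci_upper": 1.347, "p": 0.001},
        {"term": "SHR_CMP", "coef": 0.038, "or": 1.039, "ci_lower": 1.011, "ci_upper": 1.066, "p": 0.005}
      ]
    },
    "NP": {
      "intercept": -17.114,
      "terms": [
        {"term": "gender", "coef": 2.203, "or": 7.403, "ci_lower": 2.326, "ci_upper": 35.233, "p": 0.001},
        {"term": "pseudocapsule", "coef": 2.038, "or": 11.703, "ci_lower": 0.981, "ci_upper": 75.477, "p": 0.048},
        {"term": "RER_NP_2", "coef": 0.157, "or": 1.177, "ci_lower": 1.081, "ci_upper": 1.266, "p": 0.000},
        {"term": "HDT_NP", "coef": 0.195, "or": 1.345, "ci_lower": 1.052, "ci_upper": 1.405, "p": 0.008}
      ]
    },
    "EP": {
      "intercept": -12.019,
      "terms": [
        {"term": "gender", "coef": 2.773, "or": 16.005, "ci_lower": 4.033, "ci_upper": 65.523, "p": 0.000},
        {"term": "angular", "coef": 2.059, "or": 7.840, "ci_lower": 1.883, "ci_upper": 32.643, "p": 0.005},
        {"term": "RER_EP_2", "coef": 0.088, "or": 1.092, "ci_lower": 1.027, "ci_upper": 1.162, "p": 0.005},
        {"term": "SHR_EP", "coef": 1.788, "or": 5.978, "ci_lower": 2.066, "ci_upper": 17.292, "p": 0.001}
      ]
    }
  }
}
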