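{
  "version": 1,
  "description": "Reduction-model configuration: per-gender polynomial moment arms (m) as functions of joint angle (rad), muscle cross-sectional areas (cm^2), ligament resolution parameters, and condylar geometry. Coefficient values are documented placeholders of literature-typical magnitude; the originating regression coefficients are not reproduced here and users should substitute their preferred source. All pipeline tests are coefficient-agnostic (moment closure and round-trip properties).",
  "angle_units": "radians",
  "csa_cm2": {
    "gastrocnemius": 45.0,
    "soleus": 130.0,
    "hamstrings": 75.0,
    "gluteus_maximus": 145.0,
    "quadriceps": 180.0
  },
  "grand_mean_height_m": 1.69,
  "group_mean_height_m": { "female": 1.628, "male": 1.751 },
  "moment_arms": {
    "female": {
      "ankle": {
        "gastrocnemius": { "coef": [0.048, 0.010, -0.012], "range": [-0.7, 0.7] },
        "soleus":        { "coef": [0.052, 0.008, -0.010], "range": [-0.7, 0.7] }
      },
      "hip": {
        "hamstrings":      { "coef": [0.060, 0.015, -0.010], "range": [-0.4, 1.8] },
        "gluteus_maximus": { "coef": [0.070, 0.012, -0.008], "range": [-0.4, 1.8] }
      },
      "knee": {
        "quadriceps":    { "coef": [0.047, 0.012, -0.014], "range": [0.0, 2.3] },
        "hamstrings":    { "coef": [0.034, 0.008, -0.006], "range": [0.0, 2.3] },
        "gastrocnemius": { "coef": [0.020, 0.010, -0.008], "range": [0.0, 2.3] }
      },
      "frontal": {
        "quadriceps":    { "coef": [-0.0080, 0.0010, 0.0], "range": [0.0, 2.3] },
        "hamstrings":    { "coef": [-0.0060, 0.0008, 0.0], "range": [0.0, 2.3] },
        "gastrocnemius": { "coef": [-0.0050, 0.0005, 0.0], "range": [0.0, 2.3] },
        "ACL": { "coef": [-0.0040, 0.0, 0.0], "range": [0.0, 2.3] },
        "PCL": { "coef": [-0.0035, 0.0, 0.0], "range": [0.0, 2.3] },
        "MCL": { "coef": [-0.0045, 0.0, 0.0], "range": [0.0, 2.3] },
        "LCL": { "coef": [0.0045, 0.0, 0.0],  "range": [0.0, 2.3] }
      }
    },
    "male": {
      "ankle": {
        "gastrocnemius": { "coef": [0.048, 0.010, -0.012], "range": [-0.7, 0.7] },
        "soleus":        { "coef": [0.052, 0.008, -0.010], "range": [-0.7, 0.7] }
      },
      "hip": {
        "hamstrings":      { "coef": [0.060, 0.015, -0.010], "range": [-0.4, 1.8] },
        "gluteus_maximus": { "coef": [0.070, 0.012, -0.008], "range": [-0.4, 1.8] }
      },
      "knee": {
        "quadriceps":    { "coef": [0.050, 0.013, -0.015], "range": [0.0, 2.3] },
        "hamstrings":    { "coef": [0.036, 0.009, -0.007], "range": [0.0, 2.3] },
        "gastrocnemius": { "coef": [0.022, 0.011, -0.009], "range": [0.0, 2.3] }
      },
      "frontal": {
        "quadriceps":    { "coef": [-0.0086, 0.0011, 0.0], "range": [0.0, 2.3] },
        "hamstrings":    { "coef": [-0.0064, 0.0009, 0.0], "range": [0.0, 2.3] },
        "gastrocnemius": { "coef": [-0.0054, 0.0006, 0.0], "range": [0.0, 2.3] },
        "ACL": { "coef": [-0.0043, 0.0, 0.0], "range": [0.0, 2.3] },
        "PCL": { "coef": [-0.0038, 0.0, 0.0], "range": [0.0, 2.3] },
        "MCL": { "coef": [-0.0048, 0.0, 0.0], "range": [0.0, 2.3] },
        "LCL": { "coef": [0.0048, 0.0, 0.0],  "range": [0.0, 2.3] }
      }
    }
  },
  "ligaments": {
    "ACL": { "plane": "sagittal", "sign": "anterior",  "orientation_deg": 25.0 },
    "PCL": { "plane": "sagittal", "sign": "posterior", "orientation_deg": 30.0 },
    "MCL": { "plane": "frontal",  "sign": "medial",    "orientation_deg": 10.0 },
    "LCL": { "plane": "frontal",  "sign": "lateral",   "orientation_deg": 10.0 }
  },
  "condylar_ratio": { "female": 1.08, "male": 1.10 },
  "default_dhat_cm": { "female": 4.86, "male": 5.53 }
}
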