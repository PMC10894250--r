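{
  "combined_uci": {
    "target_column": "target",
    "positive_label": "1",
    "negative_label": "0",
    "delimiter": ",",
    "categorical_maps": {},
    "notes": "Combined UCI heart dataset: 1025 rows, 13 numeric features, target 1 = disease present."
  },
  "cleveland_uci": {
    "target_column": "target",
    "positive_label": "1",
    "negative_label": "0",
    "delimiter": ",",
    "categorical_maps": {},
    "notes": "Cleveland UCI heart dataset: 303 rows, 13 features, target 1 = disease present."
  },
  "framingham": {
    "target_column": "TenYearCHD",
    "positive_label": "1",
    "negative_label": "0",
    "delimiter": ",",
    "categorical_maps": {},
    "notes": "Framingham heart study export: 4133-4240 rows, 15 feature columns, ten-year CHD outcome; contains missing cells (median-imputed on load)."
  },
  "south_african_heart": {
    "target_column": "chd",
    "positive_label": "1",
    "negative_label": "0",
    "delimiter": ",",
    "categorical_maps": {
      "famhist": {"Present": 1, "Absent": 0}
    },
    "notes": "South African (SAheart) dataset: 462 rows, 9 features; famhist coded Present=1/Absent=0."
  },
  "z_alizadeh_sani": {
    "target_column": "Cath",
    "positive_label": "Cad",
    "negative_label": "Normal",
    "delimiter": ",",
    "categorical_maps": {
      "Sex": {"Male": 1, "Fmale": 0},
      "Obesity": {"Y": 1, "N": 0},
      "CRF": {"Y": 1, "N": 0},
      "CVA": {"Y": 1, "N": 0},
      "Airway disease": {"Y": 1, "N": 0},
      "Thyroid Disease": {"Y": 1, "N": 0},
      "CHF": {"Y": 1, "N": 0},
      "DLP": {"Y": 1, "N": 0},
      "Weak Peripheral Pulse": {"Y": 1, "N": 0},
      "Lung rales": {"Y": 1, "N": 0},
      "Systolic Murmur": {"Y": 1, "N": 0},
      "Diastolic Murmur": {"Y": 1, "N": 0},
      "Dyspnea": {"Y": 1, "N": 0},
      "Atypical": {"Y": 1, "N": 0},
      "Nonanginal": {"Y": 1, "N": 0},
      "Exertional CP": {"Y": 1, "N": 0},
      "LowTH Ang": {"Y": 1, "N": 0},
      "LVH": {"Y": 1, "N": 0},
      "Poor R Progression": {"Y": 1, "N": 0},
      "VHD": {"N": 0, "mild": 1, "Moderate": 2, "Severe": 3},
      "BBB": {"N": 0, "LBBB": 1, "RBBB": 2},
      "Region RWMA": {"0": 0, "1": 1, "2": 2, "3": 3, "4": 4}
    },
    "notes": "Z-AlizadehSani dataset: 303 rows; published feature counts disagree (54 in the dataset summary vs 53 in the selection summary) - both are recorded here and the discrepancy is left unresolved."
  }
}
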