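{
  "version": 1,
  "description": "Published reference constants for nutrient diagnosis of young Eucalyptus (southern Brazil survey): regional clr norms of the balanced high-yield (TN) subpopulation, state concentration standards, TN quartile compatibility intervals, two worked-example diagnosed site profiles with their printed Low/Normal/High labels, observed concentration ranges, and DBH yield constants.",
  "part_order": ["N", "P", "K", "Mg", "Ca", "S", "B", "Cu", "Zn", "Mn", "Fe", "Fv"],
  "regional_clr_norms": {
    "n": 489,
    "age_window_yr": [0.9, 1.1],
    "provenance": "clr statistics of 489 TN specimens aged 0.9-1.1 yr",
    "mean": {
      "N": 2.9050, "P": 0.0726, "K": 2.1387, "Mg": 0.8880, "Ca": 2.0454,
      "S": 0.3053, "B": -4.8438, "Cu": -4.0882, "Zn": -2.7212, "Mn": -3.2629,
      "Fe": -0.2132, "Fv": 6.7743
    },
    "sd": {
      "N": 0.3048, "P": 0.2618, "K": 0.2878, "Mg": 0.2270, "Ca": 0.2962,
      "S": 0.3024, "B": 0.4189, "Cu": 0.3872, "Zn": 0.4089, "Mn": 0.3338,
      "Fe": 0.4754, "Fv": 0.1453
    }
  },
  "state_standards": {
    "provenance": "state concentration ranges for young Eucalyptus",
    "units": "native (macronutrients g/kg, micronutrients mg/kg)",
    "intervals": {
      "N": [15.0, 20.0], "P": [1.0, 1.3], "K": [9.0, 13.0], "Mg": [6.0, 10.0],
      "Ca": [5.0, 8.0], "S": [1.5, 2.0], "B": [30, 50], "Cu": [7, 10],
      "Zn": [35, 50], "Mn": [400, 600], "Fe": [150, 200]
    }
  },
  "tn_quartiles": {
    "provenance": "quartile (0.25, 0.75) compatibility intervals of 489 TN specimens",
    "units": "native (macronutrients g/kg, micronutrients mg/kg)",
    "intervals": {
      "N": [17.0, 25.3], "P": [1.0, 1.4], "K": [7.2, 11.5], "Mg": [2.3, 3.2],
      "Ca": [7.0, 10.2], "S": [1.2, 1.8], "B": [6, 12], "Cu": [14, 21],
      "Zn": [60, 96], "Mn": [34, 54], "Fe": [679, 1281]
    }
  },
  "sites": {
    "site1": {
      "N": 27.1, "P": 1.4, "K": 8.8, "Mg": 1.5, "Ca": 3.9, "S": 1.7,
      "B": 48.0, "Cu": 4.7, "Zn": 14.7, "Mn": 452.3, "Fe": 66.9
    },
    "site2": {
      "N": 15.0, "P": 1.3, "K": 8.2, "Mg": 3.8, "Ca": 21.2, "S": 1.4,
      "B": 1.3, "Cu": 17.9, "Zn": 151.8, "Mn": 73.8, "Fe": 1614.4
    }
  },
  "site_labels": {
    "site1": {
      "state": {
        "N": "High", "P": "High", "K": "Low", "Mg": "Low", "Ca": "Low",
        "S": "Normal", "B": "Normal", "Cu": "Low", "Zn": "Low",
        "Mn": "Normal", "Fe": "Low"
      },
      "tn": {
        "N": "High", "P": "Normal", "K": "Normal", "Mg": "Low", "Ca": "Low",
        "S": "Normal", "B": "High", "Cu": "Low", "Zn": "Low",
        "Mn": "High", "Fe": "Low"
      }
    },
    "site2": {
      "state": {
        "N": "Normal", "P": "Normal", "K": "Low", "Mg": "Low", "Ca": "High",
        "S": "Low", "B": "Low", "Cu": "High", "Zn": "High",
        "Mn": "Low", "Fe": "High"
      },
      "tn": {
        "N": "Low", "P": "Normal", "K": "Normal", "Mg": "High", "Ca": "High",
        "S": "Normal", "B": "Low", "Cu": "Normal", "Zn": "High",
        "Mn": "High", "Fe": "High"
      }
    }
  },
  "concentration_ranges": {
    "provenance": "observed min/median/max over the 1861-tree survey, native units",
    "min": {
      "N": 9.1, "P": 0.5, "K": 1.2, "Mg": 1.0, "Ca": 2.7, "S": 0.4,
      "B": 11, "Cu": 1, "Zn": 6, "Mn": 66, "Fe": 2, "Fv": 925.6
    },
    "median": {
      "N": 21.9, "P": 1.3, "K": 9.4, "Mg": 2.6, "Ca": 8.6, "S": 1.5,
      "B": 38, "Cu": 8, "Zn": 18, "Mn": 964, "Fe": 76, "Fv": 952.1
    },
    "max": {
      "N": 38.8, "P": 3.3, "K": 19.6, "Mg": 7.5, "Ca": 34.9, "S": 5.1,
      "B": 105, "Cu": 36, "Zn": 129, "Mn": 4954, "Fe": 594, "Fv": 973.3
    }
  },
  "dbh": {
    "cutoff_cm": 4.3,
    "successful_floor_cm": 5.0,
    "site1_dbh_cm": 4.06,
    "site2_dbh_cm": 1.71,
    "neighbor_dbh_cm": [5.43, 5.44]
  }
}
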