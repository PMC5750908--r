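{
  "schema_version": 1,
  "description": "Per-SBGC log-normal arsenic exposure models, Cornwall PWS survey 2011-2013. gm in ug/L; sigma_log is the SD of natural-log concentrations.",
  "strata": {
    "01": {"gm": 0.885, "sigma_log": 1.805, "n": 140},
    "02": {"gm": 0.575, "sigma_log": 1.214, "n": 93},
    "03": {"gm": 0.086, "sigma_log": 0.885, "n": 11},
    "04": {"gm": 1.213, "sigma_log": 2.542, "n": 19},
    "05": {"gm": 0.622, "sigma_log": 1.819, "n": 73},
    "06": {"gm": 0.441, "sigma_log": 1.577, "n": 69},
    "07": {"gm": 0.175, "sigma_log": 1.109, "n": 66},
    "08": {"gm": 0.083, "sigma_log": 1.040, "n": 3},
    "09": {"gm": 0.665, "sigma_log": 2.024, "n": 18},
    "10": {"gm": 0.141, "sigma_log": 0.977, "n": 16}
  }
}
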