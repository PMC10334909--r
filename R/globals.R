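# data.table non-standard evaluation columns
utils::globalVariables(c(
  "line", "indi_drug_seq", "indi_pt", "primaryid", "drug_seq", "caseid",
  "i.indi_pt", "role_cod", "drugname", "pt", "fda_dt", "caseversion",
  "prr_defined", "chi2_defined", "chi2", "ror", "ic025", "evans",
  "ror_rule", "ic_rule", "d", "a", "b", "event", "drug", ".N"
))
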