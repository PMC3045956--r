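{
  "version": "1",
  "description": "Report bundle emitted by refstab::run_pipeline(). Sections listed under required_sections must be present with the listed fields; 'diagnostics' is present only when leukocyte counts are available and is therefore not required.",
  "required_sections": {
    "parameters": ["cutoff", "alpha", "first_sample_only", "slope_method"],
    "data": ["n_genes", "n_samples_total", "n_samples_stability", "genes"],
    "genorm": ["m_values", "ranking", "best_pair", "exclusion_order", "v_series", "optimal_n"],
    "normfinder": ["disease_group"],
    "anova_disease_group": [],
    "ranking_concordance": ["method", "rho"]
  },
  "field_types": {
    "genorm.m_values": "object: gene id -> non-negative number",
    "genorm.v_series": "array of {n: integer >= 2, v: non-negative number}",
    "genorm.optimal_n": "integer or the string 'not reached'",
    "normfinder.<grouping>.stability": "object: gene id -> non-negative number",
    "ranking_concordance.rho": "number in [-1, 1]"
  }
}
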