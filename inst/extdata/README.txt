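hsct_cohort_synthetic.csv
  18-patient transplant cohort fixture. The two graft failures (days 50 and
  131), the single death, and the cohort size and follow-up spread match the
  reference cohort of the original evaluation; the death day and all
  censoring times are NOT published and are synthetic fill-in values chosen
  to give a mean follow-up near two years (range one to eight).

base_case_reference.csv
  Base-case results reported by the original economic evaluation of this
  comparison (2011 USD, 3% discounting). Per-arm QALYs use the in-text
  values (26.49 / 14.11); the results table's 26.50 is a rounding variant.
  The reported incremental direct non-medical cost (-20,541.83) does not
  equal the difference of its per-arm entries (-20,051.83); the file keeps
  the reported value, and the inconsistency is documented in the methods
  vignette. Used only as a cross-check target, never as a model input.
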