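# Diseases differentially diagnosed in males versus females, with the
# genes and chemical substances associated with those diseases.
set cohort = "FIX:cohort_sex"
select population_of_individual_organisms:cohort->disease->gene->chemical_substance
  from "/schema"
  where cohort = $cohort
  and icees.table = "patient"
  and icees.feature = "Sex"
  and icees.maximum_p_value = 0.5
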