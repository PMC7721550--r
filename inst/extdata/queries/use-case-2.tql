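# Diseases differentially diagnosed in patients living in rural versus
# urban regions, with the genes and chemical substances associated with
# those diseases.
set cohort = "FIX:cohort_residence"
select population_of_individual_organisms:cohort->disease->gene->chemical_substance
  from "/schema"
  where cohort = $cohort
  and icees.table = "patient"
  and icees.feature = "Residence"
  and icees.maximum_p_value = 0.5
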