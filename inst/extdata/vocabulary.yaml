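# Compact upper-level biomedical vocabulary used as the engine's type system.
# Single-inheritance: omitted parent means the entry attaches to the root.
root_concept: named_thing
root_predicate: related_to
concepts:
  - {name: biological_entity}
  - {name: gene, parent: biological_entity}
  - {name: protein, parent: biological_entity}
  - {name: cell, parent: biological_entity}
  - {name: anatomical_entity, parent: biological_entity}
  - {name: disease}
  - {name: genetic_condition, parent: disease}
  - {name: phenotypic_feature}
  - {name: chemical_substance}
  - {name: drug, parent: chemical_substance}
  - {name: metabolite, parent: chemical_substance}
  - {name: population_of_individual_organisms}
  - {name: environmental_feature}
  - {name: biological_process}
  - {name: pathway, parent: biological_process}
predicates:
  - {name: association}
  - {name: associated_with, parent: association}
  - {name: gene_associated_with_condition, parent: association}
  - {name: affects}
  - {name: increases_activity_of, parent: affects}
  - {name: decreases_activity_of, parent: affects}
  - {name: interacts_with}
  - {name: directly_interacts_with, parent: interacts_with}
  - {name: treats}
  - {name: has_phenotype}
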