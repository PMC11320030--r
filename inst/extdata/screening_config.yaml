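rounding_dp: 2
top_k: 3
criteria:
- id: care_pathway
  description: Potential to improve the care pathway
  scale:
  - code: 0
    label: No/Very low potential
  - code: 1
    label: Low potential
  - code: 2
    label: Moderate potential
  - code: 3
    label: High potential
  weight: 7.2
  weight_summary:
    mean: 7.2
    median: 7.0
    minimum: 3
    maximum: 10
    n_respondents: 15
- id: diagnostic_accuracy
  description: Certainty of evidence for diagnostic accuracy
  scale:
  - code: 0
    label: Absent
  - code: 1
    label: Very low
  - code: 2
    label: Low
  - code: 3
    label: Moderate
  - code: 4
    label: High
  weight: 8.8
  satisfice:
  - 0
  - 1
  - 2
  weight_summary:
    mean: 8.8
    median: 9.0
    minimum: 6
    maximum: 10
    n_respondents: 15
- id: clinical_effectiveness
  description: Certainty of evidence for clinical effectiveness
  scale:
  - code: 0
    label: Absent
  - code: 1
    label: Very low
  - code: 2
    label: Low
  - code: 3
    label: Moderate
  - code: 4
    label: High
  weight: 7.0
  satisfice:
  - 4
  weight_summary:
    mean: 7.0
    median: 8.0
    minimum: 2
    maximum: 10
    n_respondents: 15
- id: population_size
  description: Size of the population affected
  scale:
  - code: 0
    label: <1%
  - code: 1
    label: 2.9%
  - code: 3
    label: 4.9%
  - code: 4
    label: '>=5%'
  weight: 5.9
  weight_summary:
    mean: 5.9
    median: 6.0
    minimum: 2
    maximum: 9
    n_respondents: 15
options:
- id: lactate_trauma
  label: Lactate testing in trauma
- id: sars_cov2_rti
  label: SARS-CoV-2 testing in suspected respiratory tract infection
- id: lactate_sepsis
  label: Lactate testing in sepsis
- id: troponin_ami
  label: Troponin for acute myocardial infarction
- id: coag_trauma
  label: Coagulation testing in trauma
- id: bloodgas_copd
  label: Blood gas testing in COPD
- id: ketones_dka
  label: Blood ketone testing to diagnose diabetic ketoacidosis
- id: ntprobnp_hf
  label: NT-proBNP to identify heart failure
- id: ntprobnp_sepsis
  label: NT-proBNP to identify sepsis
- id: crp_sepsis
  label: C-reactive protein (CRP) testing in sepsis
- id: bhcg_pregnancy
  label: Beta-HCG testing to identify pregnancy
- id: tbi_biomarkers
  label: Biomarkers of traumatic brain injury
exclude:
- coag_trauma
- bloodgas_copd
- ntprobnp_hf
- ntprobnp_sepsis
- crp_sepsis
- bhcg_pregnancy
- tbi_biomarkers
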