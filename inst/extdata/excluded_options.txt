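# options excluded by panel decision
coag_trauma
bloodgas_copd
ntprobnp_hf
ntprobnp_sepsis
crp_sepsis
bhcg_pregnancy
tbi_biomarkers
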