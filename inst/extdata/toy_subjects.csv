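subject_id,baseline_group,conversion_month,followup_month
s1,MCI,12,36
s2,CN,,24
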