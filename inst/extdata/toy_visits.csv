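subject_id,modality,visit_month,f1,f2,f3,f4,f5
s1,cognitive,0,0.5,-0.2,,,
s1,cognitive,6,0.1,-0.6,,,
s2,demographics,0,70,1,16,0,
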