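measurement_id,lesion_id,patient_id,label,stage
les1_m1,LES1,PAT1,pigmented,raw
les1_m2,LES1,PAT1,pigmented,raw
les2_m1,LES2,PAT2,melanoma,raw
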