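measurement_id,800,998,1196,1394,1592,1790
les1_m1,0.5,1.25,0.875,1.5,0.75,0.25
les1_m2,0.5,1.125,1,1.375,0.75,0.25
les2_m1,0.25,0.75,1.625,0.875,0.5,0.375
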