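indicator,reference_value,lit_mean,lit_sd,source
L5 cortical peak stress (MPa),815,820,30,Ke et al. 2021
L4-L5 disc peak stress (MPa),36.9,37.5,2.0,Zhao et al. 2023
L5 trabecular peak stress (MPa),2.6,2.5,0.3,Spina et al. 2021
Lumbar compression stiffness (N/mm),1250,1230,50,Ke et al. 2021
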