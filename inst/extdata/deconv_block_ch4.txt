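DECONVOLUTION: target_mz=15 ; target_species=CH4 ; detector=F ; MS_EE=70 eV ; basis=((’CH4’, 14,0.103, 15,0.806, 16,1.0), (’N2’, 14,0.059, 15,0.00012, 28,1.0), (’AIR’, 14,0.059, 15,0.00014, 16,0.0158, 28,1.0, 32,0.208))
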