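DECONVOLUTION: target_mz=20 ; target_species=NE20 ; detector=M ; MS_EE=45 eV ; basis=((’H2O’, 17,0.164, 18,1.0, 20,0.00134), (’NE20’, 20,1.0), (’AR’, 20,1.06e-09, 36,0.003, 40,1.0))
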