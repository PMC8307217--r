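assay,species,inhibition_level,ic_ug_ml,te_umol_g
ABTS,Scenedesmus obliquus,50,29.4,637.5
ABTS,Nannochloropsis oceanica,50,101.9,184.0
DPPH,Chlorella vulgaris,20,50.5,191.8
DPPH,Scenedesmus obliquus,20,89.1,114.5
DPPH,Tetraselmis chui,20,225.7,45.0
DPPH,Nannochloropsis oceanica,20,175.6,52.5
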