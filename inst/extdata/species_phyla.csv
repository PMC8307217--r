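species,abbrev,phylum
Chlorella vulgaris,C.v,Chlorophyta
Chlorococcum amblystomatis,C,Chlorophyta
Scenedesmus obliquus,SC,Chlorophyta
Tetraselmis chui,T.C,Chlorophyta
Phaeodactylum tricornutum,Phae,Bacillariophyta
Spirulina sp.,SP,Cyanobacteria
Nannochloropsis oceanica,N.O,Ochrophyta
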