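clade,rank,extant_species
Alphidae,family,120
Betidae,family,45
Alphoidea,superfamily,120
Betoidea,superfamily,45
Alphomorpha,infraorder,120
Betomorpha,infraorder,45
Alphoptera,suborder,120
Betoptera,suborder,45
Synthetica,order,165
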