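species,family,superfamily,infraorder,suborder,deposit,stage,age_older,age_younger
Alpha primaeva,Alphidae,Alphoidea,Alphomorpha,Alphoptera,D_perm1,Kungurian,283.5,273.01
Alpha primaeva,Alphidae,Alphoidea,Alphomorpha,Alphoptera,D_perm2,Kungurian,280,275
Alpha secunda,Alphidae,Alphoidea,Alphomorpha,Alphoptera,D_perm2,Roadian,273.01,266.9
Alpha tertia,Alphidae,Alphoidea,Alphomorpha,Alphoptera,D_tri1,Carnian,237,227
Alpha quarta,Alphidae,Alphoidea,Alphomorpha,Alphoptera,D_jur1,Toarcian,184.2,174.7
Alpha quinta,Alphidae,Alphoidea,Alphomorpha,Alphoptera,D_cre1,Albian,113,100.5
Alpha quinta,Alphidae,Alphoidea,Alphomorpha,Alphoptera,D_cre2,Cenomanian,100.5,93.9
Alpha sexta,Alphidae,Alphoidea,Alphomorpha,Alphoptera,D_pal1,Ypresian,56,47.8
Alpha septima,Alphidae,Alphoidea,Alphomorpha,Alphoptera,D_neo1,Burdigalian,20.44,15.97
Alphella una,Alphellidae,Alphoidea,Alphomorpha,Alphoptera,D_tri2,Norian,227,208.5
Alphella duo,Alphellidae,Alphoidea,Alphomorpha,Alphoptera,D_jur1,Toarcian,184.2,174.7
Alphella tria,Alphellidae,Alphoidea,Alphomorpha,Alphoptera,D_jur2,Oxfordian,161.5,154.8
Alphella quattuor,Alphellidae,Alphoidea,Alphomorpha,Alphoptera,D_cre1,Albian,113,100.5
Prima antiqua,Primidae,Primoidea,Alphomorpha,Alphoptera,D_perm3,Asselian,298.9,293.52
Prima media,Primidae,Primoidea,Alphomorpha,Alphoptera,D_perm4,Artinskian,290.1,283.5
Prima ultima,Primidae,Primoidea,Alphomorpha,Alphoptera,D_perm5,Wuchiapingian,259.51,254.14
Gamma vetusta,Gammidae,Gammoidea,Gammomorpha,Alphoptera,D_perm3,Asselian,298.9,293.52
Gamma posterior,Gammidae,Gammoidea,Gammomorpha,Alphoptera,D_tri1,Carnian,237,227
Beta prisca,Betidae,Betoidea,Betomorpha,Betoptera,D_cre3,Aptian,121.4,113
Beta media,Betidae,Betoidea,Betomorpha,Betoptera,D_cre2,,100.5,93.9
Beta recens,Betidae,Betoidea,Betomorpha,Betoptera,D_pal1,Ypresian,56,47.8
Beta nova,Betidae,Betoidea,Betomorpha,Betoptera,D_neo2,Langhian,15.97,13.82
Betella jurassica,Betellidae,Betoidea,Betomorpha,Betoptera,D_jur2,Oxfordian,161.5,154.8
Betella cretacea,Betellidae,Betoidea,Betomorpha,Betoptera,D_cre3,Aptian,121.4,113
Betella extrema,Betellidae,Betoidea,Betomorpha,Betoptera,D_cre1,Albian,113,100.5
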