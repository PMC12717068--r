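interval,variable,level,n_advanced,n_no_advanced
annual,race_ethnicity,Asian,72,237823
annual,race_ethnicity,Black,192,228253
annual,race_ethnicity,Hispanic,48,116719
annual,race_ethnicity,White,736,1797793
annual,race_ethnicity,Other/Multiple,22,42626
annual,race_ethnicity,Unknown,40,118053
biennial,race_ethnicity,Asian,88,102763
biennial,race_ethnicity,Black,103,66261
biennial,race_ethnicity,Hispanic,40,47418
biennial,race_ethnicity,White,493,487396
biennial,race_ethnicity,Other/Multiple,19,18856
biennial,race_ethnicity,Unknown,17,28591
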