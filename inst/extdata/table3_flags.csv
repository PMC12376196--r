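category_group,type,study,uniform_benefits,other_modifications,costs_computed,demonstration_stage
environmental,availability,Miller and Levy 2000,FALSE,FALSE,FALSE,TRUE
environmental,availability,Miller 2001; Kypri et al. 2006,TRUE,FALSE,FALSE,FALSE
environmental,availability,Miller 2001,FALSE,TRUE,FALSE,TRUE
environmental,availability,Elder et al. 2007,FALSE,FALSE,TRUE,FALSE
environmental,availability,Campbell 2009; Norstrom 2010,FALSE,FALSE,TRUE,FALSE
environmental,availability,Hahn et al. 2010; Middleton 2010,FALSE,FALSE,TRUE,FALSE
environmental,availability,Rammohan et al. 2011,FALSE,FALSE,TRUE,FALSE
environmental,marketing,Cobiac et al. 2009,TRUE,TRUE,FALSE,FALSE
environmental,marketing,Norstrom et al. 2010,FALSE,FALSE,TRUE,FALSE
environmental,pricing,Meng 2013,TRUE,TRUE,FALSE,FALSE
environmental,pricing,Byrnes 2012,TRUE,FALSE,TRUE,FALSE
environmental,pricing,Byrnes 2012,TRUE,FALSE,TRUE,FALSE
environmental,pricing,Byrnes 2012,TRUE,FALSE,TRUE,FALSE
environmental,pricing,Byrnes 2010,TRUE,FALSE,TRUE,FALSE
environmental,drink_driving,Miller and Levy 2000,FALSE,FALSE,FALSE,FALSE
environmental,drink_driving,Miller and Levy 2000,FALSE,FALSE,FALSE,FALSE
environmental,drink_driving,Miller and Levy 2000,TRUE,FALSE,FALSE,FALSE
environmental,drink_driving,Miller 2001,FALSE,FALSE,FALSE,FALSE
environmental,drink_driving,Miller 2001,FALSE,FALSE,FALSE,FALSE
environmental,drink_driving,Elder 2004,FALSE,FALSE,TRUE,FALSE
environmental,drink_driving,Fell 2008,FALSE,FALSE,TRUE,FALSE
environmental,drink_driving,Miller and Hendrie 2013,FALSE,FALSE,FALSE,FALSE
environmental,drink_driving,Miller and Hendrie 2013,FALSE,FALSE,FALSE,FALSE
environmental,drink_driving,Miller and Hendrie 2013,FALSE,FALSE,FALSE,FALSE
environmental,drink_driving,WSIPP 2017,TRUE,FALSE,FALSE,FALSE
environmental,drink_driving,Teoh 2018,FALSE,FALSE,TRUE,FALSE
environmental,drink_driving,Miller 2020,FALSE,FALSE,TRUE,FALSE
workplace,workplace,Cook et al. 2003,FALSE,FALSE,TRUE,FALSE
workplace,workplace,Bennett et al. 2004,FALSE,FALSE,TRUE,FALSE
workplace,workplace,Bennett et al. 2010,FALSE,FALSE,TRUE,FALSE
workplace,workplace,Spicer and Miller 2016,FALSE,FALSE,TRUE,FALSE
health_sector,brief_interventions,WSIPP 2017,TRUE,FALSE,FALSE,FALSE
health_sector,brief_interventions,WSIPP 2017,TRUE,FALSE,FALSE,FALSE
health_sector,brief_interventions,WSIPP 2017,TRUE,FALSE,FALSE,FALSE
community,youth_development,Aos 2004 et al.,FALSE,FALSE,TRUE,FALSE
community,youth_development,Hansen et al. 2004,FALSE,FALSE,TRUE,FALSE
community,youth_development,Hansen et al. 2004,FALSE,FALSE,TRUE,FALSE
community,youth_development,Kuklinski et al. 2015,TRUE,FALSE,FALSE,TRUE
community,youth_development,Spoth et al. 2002; WSIPP 2017,TRUE,TRUE,FALSE,TRUE
community,youth_development,WSIPP 2017,FALSE,FALSE,TRUE,FALSE
community,youth_development,WSIPP 2017,FALSE,FALSE,TRUE,FALSE
community,youth_development,WSIPP 2017,TRUE,TRUE,FALSE,TRUE
community,school_based,Aos et al. 2004,FALSE,FALSE,TRUE,TRUE
community,school_based,WSIPP 2017,FALSE,FALSE,TRUE,TRUE
community,school_based,WSIPP 2017,TRUE,TRUE,FALSE,TRUE
community,school_based,Beets 2009; WSIPP 2017,TRUE,FALSE,FALSE,TRUE
community,school_based,WSIPP 2017,TRUE,TRUE,FALSE,TRUE
community,school_based,WSIPP 2017,TRUE,TRUE,FALSE,TRUE
community,school_based,WSIPP 2017,FALSE,FALSE,TRUE,TRUE
community,school_based,WSIPP 2017,FALSE,FALSE,FALSE,FALSE
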