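category_group,type,study,intervention,rating
environmental,availability,Miller and Levy 2000,Enforcing laws against serving intoxicated patrons,B
environmental,availability,Miller 2001; Kypri et al. 2006,Raising minimum legal drinking age to 19 yrs,A
environmental,availability,Miller 2001,Mandatory server training to deny service to intoxicated and underage patrons,C
environmental,availability,Elder et al. 2007,Enforce underage drinking laws,C
environmental,availability,Campbell 2009; Norstrom 2010,10% alcohol outlet density reduction,B
environmental,availability,Hahn et al. 2010; Middleton 2010,10 fewer sales hours/week,B
environmental,availability,Rammohan et al. 2011,Licensed establishment liability for harm caused by over-servicing patrons,B
environmental,marketing,Cobiac et al. 2009,Alcohol advertising ban,B
environmental,marketing,Norstrom et al. 2010,TV alcohol advertising ban,C
environmental,pricing,Meng 2013,Minimum price for alcohol of A$0.95 per drink,C
environmental,pricing,Byrnes 2012,"Same tax per liter of ethanol on all alcohol, no change in total liters sold",B
environmental,pricing,Byrnes 2012,"Same tax per liter of ethanol on all alcohol, no change in total tax revenue",B
environmental,pricing,Byrnes 2012,Spirits tax per liter of ethanol on all alcohol,B
environmental,pricing,Byrnes 2010,"Equal tax rate for beer and wine, higher rate for spirits and premised drinks",A
environmental,drink_driving,Miller and Levy 2000,Administrative license revocation,A
environmental,drink_driving,Miller and Levy 2000,Law to allow administrative license revocation based on breath testing,A
environmental,drink_driving,Miller and Levy 2000,Alcohol testing ignition interlock permitted,A
environmental,drink_driving,Miller 2001,Intensive random breath testing,A
environmental,drink_driving,Miller 2001,Zero alcohol tolerance for drivers under 18 yrs,A
environmental,drink_driving,Elder 2004,Mass media campaign to reduce drink driving,B
environmental,drink_driving,Fell 2008,Saturation patrols plus media campaign,C
environmental,drink_driving,Miller and Hendrie 2013,Vehicle impoundment for drink driving offenses,A
environmental,drink_driving,Miller and Hendrie 2013,Electronic house arrest for drink driving offenses,A
environmental,drink_driving,Miller and Hendrie 2013,Intensive probation for drink driving offenses plus treatment,A
environmental,drink_driving,WSIPP 2017,Driving under the influence court,A
environmental,drink_driving,Teoh 2018,Alcohol testing ignition interlock mandated for all offenders,B
environmental,drink_driving,Miller 2020,Subsidized Ridesharing,B
workplace,workplace,Cook et al. 2003,Prime for Life employer-sponsored web-based health promotion program,B
workplace,workplace,Bennett et al. 2004,Team Awareness program for retail and restaurant workers,B
workplace,workplace,Bennett et al. 2010,Team Resilience adaptation of Team Awareness for workers under age 26,B
workplace,workplace,Spicer and Miller 2016,PREVENT facilitated small-group employee discussions for young workers,B
health_sector,brief_interventions,WSIPP 2017,Screening for heavy drinking in primary care setting,A
health_sector,brief_interventions,WSIPP 2017,Screening for heavy drinking in hospital inpatient setting,A
health_sector,brief_interventions,WSIPP 2017,Screening for heavy drinking in emergency department care setting,A
community,youth_development,Aos 2004 et al.,Adolescent Transitions parenting skills program,A
community,youth_development,Hansen et al. 2004,Across Ages mentoring and community service program,A
community,youth_development,Hansen et al. 2004,Social Competence Promotion,C
community,youth_development,Kuklinski et al. 2015,Communities That Care,B
community,youth_development,Spoth et al. 2002; WSIPP 2017,Strengthening Families Program,A
community,youth_development,WSIPP 2017,Caring School Community,C
community,youth_development,WSIPP 2017,Good Behavior Game,B
community,youth_development,WSIPP 2017,Guiding Good Choices (Preparing for Drugfree Years),A
community,school_based,Aos et al. 2004,Family Matters,B
community,school_based,WSIPP 2017,All Stars,B
community,school_based,WSIPP 2017,Life Skills Training,A
community,school_based,Beets 2009; WSIPP 2017,Positive Action,A
community,school_based,WSIPP 2017,Project Northland,B
community,school_based,WSIPP 2017,Project STAR,B
community,school_based,WSIPP 2017,Project Toward No Drugs,B
community,school_based,WSIPP 2017,Too Good for drugs,B
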