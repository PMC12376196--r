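row_id,intervention_id,name,category,cost_per_unit,denominator,resource_savings,intangible_savings,total_savings,bcr_printed,icer_printed,quality_rating,demonstration_stage,flags
adolescent_transitions,adolescent_transitions,"Adolescent Transitions parenting skills program, ages 10-18",youth_development,2035,student,456,2804,3260,1.6,134413,A,FALSE,costs_computed
across_ages,across_ages,"Across Ages mentoring and community service program, ages 9-13",youth_development,2930,student,503,3008,3511,1.2,194624,A,FALSE,costs_computed
social_competence_promotion,social_competence_promotion,"Social Competence Promotion, ages 11-14",youth_development,593,student,511,3140,3651,6.2,6232,C,FALSE,costs_computed
communities_that_care,communities_that_care,Communities That Care needs assessment and evidence-based youth interventions,youth_development,819,student,195,3598,3793,4.6,40145,B,TRUE,uniform_benefits;demonstration_discount
strengthening_families,strengthening_families,"Strengthening Families Program parent-child behavioral training, ages 12-13",youth_development,1479,student,1783,29469,31252,21.1,NET_SAVING,A,TRUE,uniform_benefits;other_modifications;demonstration_discount
caring_school_community,caring_school_community,"Caring School Community program, ages 9-13",youth_development,388,student,643,3350,3993,10.3,NET_SAVING,C,FALSE,costs_computed
good_behavior_game,good_behavior_game,"Good Behavior Game classroom management strategy, ages 6-9",youth_development,102,student,46,3157,3203,31.4,4064,B,FALSE,costs_computed
guiding_good_choices,guiding_good_choices,"Guiding Good Choices parent-child behavioral training, ages 12-13",youth_development,1194,student,999,4325,5324,4.5,10830,A,TRUE,uniform_benefits;other_modifications;demonstration_discount
family_matters,family_matters,"Family Matters family-focused tobacco and alcohol program, ages 12-14",school_based,265,student,412,8039,8451,31.9,NET_SAVING,B,TRUE,costs_computed;demonstration_discount
all_stars,all_stars,"All Stars decision-making and peer pressure resistance training, ages 11-14",school_based,236,student,554,10146,10700,45.3,NET_SAVING,B,TRUE,costs_computed;demonstration_discount
life_skills_training,life_skills_training,"Life Skills Training three-year program, ages 13-16",school_based,375,student,241,4591,4832,12.9,6756,A,TRUE,uniform_benefits;other_modifications;demonstration_discount
positive_action_3_8,positive_action,"Positive Action school-wide positive behavior program, grades 3-8",school_based,1969,student,3545,37310,40855,20.7,NET_SAVING,A,TRUE,uniform_benefits;demonstration_discount
positive_action_3_5,positive_action,"Positive Action school-wide positive behavior program, grades 3-5",school_based,1063,student,936,12765,13701,12.9,2321,A,TRUE,uniform_benefits;demonstration_discount
project_northland,project_northland,"Project Northland school-based child-parent training, ages 12-15",school_based,670,student,328,9003,9331,13.9,8754,B,TRUE,uniform_benefits;other_modifications;demonstration_discount
project_star,project_star,"Project STAR school, family, community and media program, ages 12-15",school_based,670,student,227,5640,5867,8.8,18195,B,TRUE,uniform_benefits;other_modifications;demonstration_discount
project_toward_no_drugs,project_toward_no_drugs,"Project Toward No Drugs, ages 15-19",school_based,303,student,308,1218,1526,5.0,0,B,TRUE,costs_computed;demonstration_discount
too_good_for_drugs,too_good_for_drugs,"Too Good for Drugs school-based life skills, ages 12-14",school_based,139,student,98,583,681,4.9,16934,B,FALSE,
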