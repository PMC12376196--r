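row_id,intervention_id,name,category,cost_per_unit,denominator,resource_savings,intangible_savings,total_savings,bcr_printed,icer_printed,quality_rating,demonstration_stage,flags
serving_intoxicated_enforcement,serving_intoxicated_enforcement,Enforce laws against serving intoxicated patrons,availability,1,driver,8,27,35,35.0,NET_SAVING,B,TRUE,demonstration_discount
mlda_19,mlda_19,Raise minimum legal drinking age to 19 years,availability,401,youth,142,679,821,2.0,69355,A,FALSE,uniform_benefits
server_training,server_training,Mandatory server training to deny service to intoxicated and underage patrons,availability,100,driver,37,185,222,2.2,62231,C,TRUE,other_modifications;demonstration_discount
establishment_liability,establishment_liability,Licensed establishment liability for harm caused by over-servicing patrons,availability,6,adult,5,20,25,4.2,8788,B,FALSE,costs_computed
underage_drinking_enforcement,underage_drinking_enforcement,Enforce underage drinking laws,availability,4,youth,31,153,184,46.0,NET_SAVING,C,FALSE,costs_computed
outlet_density_reduction,outlet_density_reduction,10% alcohol outlet density reduction,availability,3095,per-1e6-population,2410,13626,16036,5.2,9151,B,FALSE,costs_computed
fewer_sales_hours,fewer_sales_hours,10% fewer sales hours per week,availability,7792,per-1e6-population,6026,34064,40090,5.1,9432,B,FALSE,costs_computed
advertising_ban,advertising_ban,Alcohol advertising ban,marketing,1329,per-1e6-population,2167,7976,10144,7.6,NET_SAVING,B,FALSE,uniform_benefits;other_modifications
tv_advertising_ban,tv_advertising_ban,TV alcohol advertising ban,marketing,12372,per-1e6-population,9643,54501,64144,5.2,9114,C,FALSE,costs_computed
minimum_price,minimum_price,Minimum price for alcohol of A$0.95 per drink,pricing,10,drinker-year,12,16,28,2.8,NET_SAVING,C,FALSE,uniform_benefits;other_modifications
volumetric_tax_same_revenue,volumetric_tax_same_revenue,"Volumetric tax on alcohol, same total tax revenue",pricing,-10,per-1e4-drinks,1,6,7,NO_COST,NET_SAVING,B,FALSE,uniform_benefits;costs_computed
volumetric_tax_same_deadweight,volumetric_tax_same_deadweight,"Volumetric tax on alcohol, same deadweight loss",pricing,0.04,per-1e4-drinks,11,51,61,1537,NET_SAVING,B,FALSE,uniform_benefits;costs_computed
volumetric_tax_spirits_rate,volumetric_tax_spirits_rate,Volumetric tax on alcohol at spirits tax rate,pricing,151,per-1e4-drinks,1651,7913,9564,63,NET_SAVING,B,FALSE,uniform_benefits;costs_computed
wine_excise_at_beer_rate,wine_excise_at_beer_rate,Replace price-based wine tax with excise tax at beer rate,pricing,3,per-1e4-drinks,5,22,27,8.8,NET_SAVING,A,FALSE,uniform_benefits;costs_computed
admin_license_revocation,admin_license_revocation,Administrative license revocation,drink_driving,4330,license-revoked,5265,30105,35370,8.2,NET_SAVING,A,FALSE,
admin_revocation_breath_testing,admin_revocation_breath_testing,Law to allow administrative license revocation based on breath testing,drink_driving,4065,license-revoked,6269,35797,42066,10.3,NET_SAVING,A,FALSE,
ignition_interlock_permitted,ignition_interlock_permitted,Alcohol-testing ignition interlock permitted,drink_driving,1912,vehicle-equipped,739,4041,4780,2.5,52855,A,FALSE,uniform_benefits
rbt_rate_increase,rbt_rate_increase,Raise random breath test rate from 0.5 to 1 per driver per year,drink_driving,21,driver,22,91,113,5.5,NET_SAVING,A,FALSE,
zero_tolerance_under18,zero_tolerance_under18,Zero alcohol tolerance for drivers under 18 years,drink_driving,78,driver,93,471,564,7.2,NET_SAVING,A,FALSE,
mass_media_campaign,mass_media_campaign,Mass media campaign to reduce drink driving,drink_driving,5389,per-1e3-population,5446,20056,25502,4.7,NET_SAVING,B,FALSE,costs_computed
saturation_patrols,saturation_patrols,Saturation patrols plus media campaigns,drink_driving,51406,per-1e4-drivers,40487,167137,207624,4.0,11890,C,FALSE,costs_computed
vehicle_impoundment,vehicle_impoundment,Vehicle impoundment for drink driving offenses,drink_driving,1648,impoundment,603,2646,3248,2.0,71874,A,FALSE,
electronic_house_arrest,electronic_house_arrest,Electronic house arrest for drink driving offenses,drink_driving,2868,house-arrest,1960,1619,3579,1.2,102161,A,FALSE,
intensive_probation,intensive_probation,Intensive probation for drink driving offenses plus treatment,drink_driving,1511,probation,1075,2506,3581,2.4,31684,A,FALSE,
dui_court,dui_court,Driving under the influence court,drink_driving,3092,client,163,6846,7009,2.3,77853,A,FALSE,uniform_benefits
ignition_interlock_mandated,ignition_interlock_mandated,Alcohol testing ignition interlock mandated for all offenders,drink_driving,1912,vehicle-equipped,1794,9814,11608,6.1,NET_SAVING,B,FALSE,costs_computed
prime_for_life,prime_for_life,Prime for Life employer-sponsored web-based health promotion program,workplace,19,participating-worker,55,299,354,18.2,NET_SAVING,B,FALSE,costs_computed
team_awareness,team_awareness,Team Awareness program for retail and restaurant workers,workplace,268,participating-worker,228,1245,1473,5.5,5828,B,FALSE,costs_computed
team_resilience,team_resilience,Team Resilience adaptation of Team Awareness for workers under age 26,workplace,269,participating-worker,445,2421,2865,10.6,NET_SAVING,B,FALSE,costs_computed
prevent_program,prevent_program,PREVENT facilitated small-group employee discussions for young workers,workplace,494,participating-worker,209,1180,1389,2.8,43918,B,FALSE,costs_computed
sbi_primary_care,sbi_primary_care,"Screening for heavy drinking in primary care, brief motivational intervention",health_sector,353,person-treated,439,3872,4311,12.2,NET_SAVING,A,FALSE,uniform_benefits
sbi_hospital,sbi_hospital,"Screening for heavy drinking in hospital inpatient setting, brief motivational intervention",health_sector,129,person-treated,382,3376,3758,29.0,NET_SAVING,A,FALSE,uniform_benefits
sbi_emergency,sbi_emergency,"Screening for heavy drinking in emergency department, brief motivational intervention",health_sector,350,person-treated,313,2761,3074,8.8,2460,A,FALSE,uniform_benefits
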