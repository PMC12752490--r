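# Per-animal metadata for the emulated eight-dolphin feeding study.
# intake_kcal_2/pct_daily_2 give the second caloric level for the two animals
# tested at two intakes; NA otherwise. pct_daily columns are the meal as a
# percentage of total daily intake. age flagged estimated where birthdate
# was unknown.
animal_id,sex,age_yr,age_estimated,mass_kg,intake_kcal,pct_daily,intake_kcal_2,pct_daily_2,location,maturity
Tt1,M,38,TRUE,185.6,2658,35,NA,NA,O,adult
Tt2,M,9,FALSE,188.3,2658,16,NA,NA,O,adult
Tt3,M,10,FALSE,177.9,1798,18,2658,24,O,adult
Tt4,M,17,TRUE,172.0,1798,24,2658,37,O,adult
Tt5,F,38,TRUE,200.6,2658,25,NA,NA,O,adult
Tt6,F,40,TRUE,156.6,1798,20,NA,NA,K,adult
Tt7,M,5,TRUE,149.5,1659,18,NA,NA,K,juvenile
Tt8,M,39,TRUE,240.9,2221,19,NA,NA,K,adult
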