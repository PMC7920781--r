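plant,pollinator,guild,location,year,season,sample_id,floral_abundance,count
Hamelia patens,Trigona fulviventris,bee,loc_1,2017,rainy,loc_1_2017_rainy_Ham_s01,120,3
Hamelia patens,Apis mellifera,bee,loc_1,2017,rainy,loc_1_2017_rainy_Ham_s01,120,1
Hamelia patens,Urbanus dorantes,butterfly,loc_2,2017,rainy,loc_2_2017_rainy_Ham_s01,95,1
Turnera subulata,Trigona fulviventris,bee,loc_1,2017,rainy,loc_1_2017_rainy_Tur_s01,310,2
Turnera subulata,Halictus sp1,bee,loc_1,2017,rainy,loc_1_2017_rainy_Tur_s01,310,4
Turnera subulata,Halictus sp1,bee,loc_2,2018,rainy,loc_2_2018_rainy_Tur_s01,280,2
Lantana camara,Urbanus dorantes,butterfly,loc_2,2018,rainy,loc_2_2018_rainy_Lan_s01,60,1
Lantana camara,Apis mellifera,bee,loc_2,2017,dry,loc_2_2017_dry_Lan_s01,45,2
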