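unit_id,indicator_id,value
AES1,land_suitability,2.5
AES2,land_suitability,4.2
AES3,land_suitability,4.0
AES4,land_suitability,3.0
AES5,land_suitability,1.8
AES1,landuse_sustainability,1.5
AES2,landuse_sustainability,2.5
AES3,landuse_sustainability,2.5
AES4,landuse_sustainability,2.0
AES5,landuse_sustainability,1.2
AES1,land_cover_change,-15
AES2,land_cover_change,-5
AES3,land_cover_change,-6
AES4,land_cover_change,-10
AES5,land_cover_change,-20
AES1,irrigation_potential,120
AES2,irrigation_potential,300
AES3,irrigation_potential,260
AES4,irrigation_potential,180
AES5,irrigation_potential,90
AES1,production_total,1.8
AES2,production_total,2.6
AES3,production_total,2.4
AES4,production_total,2.2
AES5,production_total,1.2
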