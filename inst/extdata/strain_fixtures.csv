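strain_id,parent,mu,q_co2,biomass_conc,total_carotenoids,frac_beta_carotene,frac_lycopene,frac_phytoene,ionone_titer,culture_time,glucose_uptake_exp
bCar1.1,CEN.PK2-1c,,,,4,,,,,72,
bCar1.2,CEN.PK2-1c,,,,3.8,,,,,72,
bCar2.1,CEN.PK2-1c,,,,3.8,,,,,72,
bCar3,bCar2.1,,,,12,,,,,72,
bCar4.b,bCar3,,,,16,,,,,72,
bCar5,bCar4.b,,,,32,,,,,72,
iono2.1,bCar2.1,,,,,,,,1.8,72,
iono4.1,bCar4.b,,,,14.2,,,,,72,
iono5.1,bCar5,,,,26.7,,,,18.2,72,
iono5.2,iono5.1,,,,,,,,26.3,72,
iono5.3,iono5.2,,,,,,,,33,72,
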