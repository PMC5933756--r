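symbol,value,units,description
imax,0.09,g feed g^-m d^-1,maximum ingestion rate coefficient
m,0.67,-,ingestion allometric exponent on wet weight
topt_ana,26,degC,optimum temperature of the anabolic response
tsig_ana,9,degC,width of the Gaussian anabolic temperature response
k_cat,65,J g^-n_cat d^-1,catabolism coefficient at the reference temperature
n_cat,0.8,-,catabolism allometric exponent on wet weight
pc_cat,0.069,degC^-1,exponential temperature coefficient of catabolism
tref_cat,20,degC,reference temperature where the catabolic response equals 1
alpha_ana,0.35,-,fraction of digested energy available for growth after feeding losses
dig_protein,0.89,-,apparent digestibility of feed protein
dig_lipid,0.94,-,apparent digestibility of feed lipid
dig_carb,0.55,-,apparent digestibility of feed carbohydrate
en_protein,23600,J g^-1,energy content of protein
en_lipid,39500,J g^-1,energy content of lipid
en_carb,17200,J g^-1,energy content of carbohydrate
eps,6500,J g^-1,energy density of fish wet tissue
oxycal,13560,J gO2^-1,oxycalorific coefficient (energy released per g O2 respired)
prot_cat_frac,0.6,-,fraction of catabolic energy fuelled by protein oxidation
n_protein,0.16,gN g^-1,nitrogen content of protein
w_commercial,350,g,default commercial wet weight
mortality,0.00041,d^-1,default natural mortality rate
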