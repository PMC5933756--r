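symbol,value,units,description
crmax,66,l d^-1 g^-b_cr,maximum clearance rate coefficient (per g dry weight^b_cr)
b_cr,0.66,-,clearance/ingestion allometric exponent on total dry weight
topt_filt,17,degC,optimum temperature of the filtration response
tsig_filt,9,degC,width of the Gaussian filtration temperature response
ing_cap,32,mgC d^-1 g^-b_cr,ingestion capacity coefficient (pseudofaeces threshold)
ae_phyto,0.45,-,absorption efficiency of phytoplankton carbon
ae_det,0.2,-,absorption efficiency of detritus and zooplankton carbon
en_food,45,J mgC^-1,energy content of assimilated organic carbon
k_cat,150,J g^-n_cat d^-1,catabolism coefficient at the reference temperature
n_cat,0.75,-,catabolism allometric exponent on somatic dry weight
pc_cat,0.074,degC^-1,exponential temperature coefficient of catabolism
tref_cat,18,degC,reference temperature where the catabolic response equals 1
eps,21000,J g^-1,energy density of dry flesh
gonad_frac,0.2,-,fraction of positive net production allocated to gonad when mature
l_mat,2.0,cm,maturity shell length (no gonad allocation below)
t_gam,12,degC,minimum temperature for gametogenesis (gonad allocation)
spawn_ratio,0.15,-,gonad/soma dry-weight ratio triggering spawning
t_spawn,14,degC,minimum temperature for spawning
aw,0.002137,g cm^-bw,length-weight coefficient (total dry weight = aw * L^bw)
bw,3,-,length-weight exponent
dry_wet,0.17,-,dry/wet ratio of soft tissue
soft_total,0.35,-,soft-tissue wet weight / total wet weight including shell
tissue_c,0.45,gC g^-1,carbon fraction of dry flesh
tissue_n,0.10,gN g^-1,nitrogen fraction of dry flesh
tissue_p,0.009,gP g^-1,phosphorus fraction of dry flesh
oxycal,13560,J gO2^-1,oxycalorific coefficient (energy released per g O2 respired)
prot_cat_frac,0.6,-,fraction of catabolic energy fuelled by protein oxidation
n_protein,0.16,gN g^-1,nitrogen content of protein
en_protein,23600,J g^-1,energy content of protein
c_to_chl,50,gC gChl^-1,carbon-to-chlorophyll ratio of phytoplankton
l_commercial,5,cm,minimum commercial shell length
l_target,7,cm,target commercial shell length
mortality,0.0005,d^-1,default natural mortality rate
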