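symbol,value,units,description
a_ana,70,J d^-1 g^-2/3,anabolism coefficient (surface-proportional food uptake)
k_chl,1.5,ug l^-1,half-saturation chlorophyll-a concentration of the food response
topt_ana,22,degC,optimum temperature of the anabolic response
tsig_ana,8,degC,width of the Gaussian anabolic temperature response
k_cat,4,J g^-n_cat d^-1,catabolism coefficient at the reference temperature
n_cat,1.0,-,catabolism allometric exponent on wet weight
pc_cat,0.07,degC^-1,exponential temperature coefficient of catabolism
tref_cat,20,degC,reference temperature where the catabolic response equals 1
eps,2000,J g^-1,energy density of wet tissue (whole animal)
aw,0.000125,g mm^-bw,length-weight coefficient (wet weight = aw * L^bw)
bw,3,-,length-weight exponent
l_commercial,25,mm,minimum commercial shell length
mortality,0.0005,d^-1,default natural mortality rate
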