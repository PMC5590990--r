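tissue,model,c1,c2,k1,k2,theta,kappa,D,mu1,a1,mu2,a2,mu3,a3
av_leaflet,mhgo,1.738,11.368,2159.4,1158.9,4.59,0.2359,1e-05,NA,NA,NA,NA,NA,NA
anterior_mv_leaflet,mhgo,0.1245,13.665,11.007,84.848,13.09,0.08,1e-05,NA,NA,NA,NA,NA,NA
posterior_mv_leaflet,mhgo,0.0502,15.004,3.021,144.48,25.51,0.0534,1e-05,NA,NA,NA,NA,NA,NA
basal_chordae,ogden,NA,NA,NA,NA,NA,NA,NA,10256.1,16.579,10653.8,16.554,10671.3,16.554
strut_chordae,ogden,NA,NA,NA,NA,NA,NA,NA,24341.7,11.338,10331.9,11.167,14913.6,11.188
marginal_chordae,ogden,NA,NA,NA,NA,NA,NA,NA,12995.5,15.651,13082.9,15.683,12869.7,15.662
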