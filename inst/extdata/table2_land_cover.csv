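group,n,model,r2,rmse,rpiq
Cropland,7476,cubist,0.67,0.32,2.06
Grassland,4200,cubist,0.64,0.34,2.02
Shrubland,443,cubist,0.79,0.45,2.25
Woodland,5218,cubist,0.82,0.45,2.81
Cropland,7476,plsr,0.60,0.35,1.88
Grassland,4200,plsr,0.59,0.38,1.80
Shrubland,443,plsr,0.77,0.45,2.25
Woodland,5218,plsr,0.79,0.49,2.58
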