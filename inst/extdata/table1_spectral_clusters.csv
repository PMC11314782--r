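group,n,model,r2,rmse,rpiq
Cluster1,3870,cubist,0.86,0.35,2.86
Cluster2,4914,cubist,0.85,0.40,2.96
Cluster3,5145,cubist,0.73,0.38,2.31
Cluster4,4992,cubist,0.87,0.42,3.67
Cluster1,3870,plsr,0.82,0.40,2.50
Cluster2,4914,plsr,0.78,0.49,2.42
Cluster3,5145,plsr,0.55,0.51,1.72
Cluster4,4992,plsr,0.81,0.50,3.08
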