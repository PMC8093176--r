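trait,sex,r_ph,a2_wb,a2_tr,e2_wb,e2_tr,bivA,bivE
optimism,F,0.403,0.444,0.311,0.556,0.689,0.663,0.337
optimism,M,0.334,0.344,0.244,0.656,0.756,0.403,0.597
anxious_depressed,F,-0.460,0.443,0.444,0.557,0.556,0.666,0.334
anxious_depressed,M,-0.337,0.364,0.394,0.654,0.606,0.649,0.351
aggressive_behavior,F,-0.238,0.444,0.495,0.556,0.505,0.706,0.294
aggressive_behavior,M,-0.096,0.344,0.459,0.656,0.541,0.699,0.301
educational_achievement,F,0.060,0.444,0.804,0.556,0.196,0.693,0.307
educational_achievement,M,0.057,0.346,0.801,0.654,0.199,0.966,0.034
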