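classifier,level,AC,PR,RC,F,MCC
GLM,5,0.543,0.474,0.450,0.462,0.066
GLM,6,0.565,0.526,0.476,0.500,0.118
GLM,7,0.565,0.632,0.480,0.545,0.148
GLM,8,0.522,0.579,0.440,0.500,0.060
GLM,9,0.587,0.579,0.500,0.537,0.169
GLM,10,0.804,0.895,0.708,0.791,0.629
SVM,5,0.913,0.842,0.941,0.889,0.821
SVM,6,0.935,0.895,0.944,0.919,0.865
SVM,7,0.935,0.895,0.944,0.919,0.865
SVM,8,0.913,0.842,0.941,0.889,0.821
SVM,9,0.913,0.895,0.895,0.895,0.821
SVM,10,0.848,0.842,0.800,0.821,0.689
CART,5,0.968,1.000,0.929,0.963,0.936
CART,6,0.968,1.000,0.929,0.963,0.936
CART,7,0.968,1.000,0.929,0.963,0.936
CART,8,0.952,0.885,1.000,0.939,0.904
CART,9,0.952,0.885,1.000,0.939,0.904
CART,10,0.790,0.846,0.710,0.772,0.588
RF,5,0.952,0.885,1.000,0.939,0.904
RF,6,0.968,0.923,1.000,0.960,0.935
RF,7,0.968,0.923,1.000,0.960,0.935
RF,8,0.952,0.885,1.000,0.939,0.904
RF,9,0.968,0.923,1.000,0.960,0.935
RF,10,0.903,0.923,0.857,0.889,0.805
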