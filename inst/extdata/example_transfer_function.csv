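"f_Hz","re_H","im_H","r0","r1","r2","significant"
1,-0.568160946271171,-0.0945506557643514,120,57.5974554449431,1,TRUE
1.29154966501488,-0.567062975982172,-0.148434843768424,120,58.6168338938835,1,TRUE
1.66810053720006,-0.579496978438077,-0.172455107749268,120,60.4613523010917,1,TRUE
2.15443469003188,-0.597493169917558,-0.235506142482343,120,64.2231446789275,1,TRUE
2.78255940220712,-0.653286149946827,-0.301928079670496,120,71.9682818334481,1,TRUE
3.59381366380463,-0.702308914285652,-0.397756128631661,120,80.7123131219232,1,TRUE
4.64158883361278,-0.795189616674884,-0.440038601959633,120,90.8823688997011,1,TRUE
5.99484250318941,-0.903908201237996,-0.510424551087298,120,103.806707809177,1,TRUE
7.74263682681127,-1.05034291079885,-0.527549990366667,120,117.538471259468,1,TRUE
10,-1.25913018212322,-0.478458912239721,120,134.697132346434,1,TRUE
12.9154966501488,-1.44552997815506,-0.356841081801603,120,148.892326041549,1,TRUE
16.6810053720006,-1.67817792244562,-0.194418266500239,120,168.940214328409,1,TRUE
21.5443469003188,-1.78829327968884,0.141661113671669,120,179.389540534195,1,TRUE
27.8255940220712,-1.76092750158705,0.448695545152467,120,181.719381412256,1,TRUE
35.9381366380463,-1.51435178203777,0.727579084871852,120,168.006923800893,1,TRUE
46.4158883361278,-1.37840084861086,1.04915476599245,120,173.225708901878,1,TRUE
59.9484250318941,-0.897566502812163,1.31999855416894,120,159.625242677295,1,TRUE
77.4263682681127,-0.486537772053155,1.4024597106543,120,148.445688507379,1,TRUE
100,-0.0192385274548749,1.24312566261891,120,124.327452077179,1,TRUE
129.154966501488,0.3449919087311,0.983215731831388,120,104.198492907079,1,TRUE
166.810053720006,0.61901757778207,0.67156634538113,120,91.3336804170153,1,TRUE
215.443469003188,0.671924317789065,0.26982456682762,120,72.4077057846756,1,TRUE
278.255940220712,0.568488534584315,-0.131005320814245,120,58.3388042417279,1,TRUE
359.381366380463,0.274560997873075,-0.353542930960848,120,44.7634164899693,1,TRUE
464.158883361278,-0.0638558665798722,-0.348470047466778,120,35.4272417326222,1,TRUE
599.484250318941,-0.251898199499067,-0.0832781036824434,120,26.53072661346,1,TRUE
774.263682681127,-0.110231550347182,0.181347439933009,120,21.2221319999193,1,TRUE
1000,0.155744117683761,0.0611586587640741,120,16.7321880622092,1,TRUE
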