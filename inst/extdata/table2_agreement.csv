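angle,side,mean_intra,sd_intra,cv_intra,mean_inter,sd_inter,cv_inter
FTA-NBC,left,22.196,0.442,1.993,22.175,1.202,5.418
FTA-NBC,right,23.766,0.623,2.622,23.818,1.374,5.77
FTA-NC,left,20.038,0.688,3.431,19.922,1.646,8.264
FTA-NC,right,20.256,0.606,2.992,20.349,1.66,8.158
FIA-NBC,left,137.84,6.1646,4.472,137.077,1.595,1.163
FIA-NBC,right,137.249,0.62,0.452,137.104,1.429,1.042
FIA-NC,left,117.918,1.119,0.949,117.593,2.079,1.768
FIA-NC,right,118.052,0.696,0.59,118.096,1.695,1.435
FVA-td,left,173.835,3.306,1.902,173.768,2.771,1.595
FVA-td,right,173.579,8.993,5.146,174.606,2.863,1.64
FVA-pd,left,176.007,3.694,2.099,175.129,1.859,1.061
FVA-pd,right,175.104,3.384,1.933,174.937,2.931,1.676
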