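bone,group,region,count,percent,n_knees
distal_femur,judo,1,0,0,30
distal_femur,judo,2,9,30,30
distal_femur,judo,3,2,7,30
distal_femur,judo,4,24,80,30
distal_femur,judo,5,30,100,30
distal_femur,judo,6,28,93,30
distal_femur,judo,7,3,10,30
distal_femur,judo,8,2,7,30
distal_femur,judo,9,3,10,30
distal_femur,control,1,4,13,30
distal_femur,control,2,2,7,30
distal_femur,control,3,6,20,30
distal_femur,control,4,12,40,30
distal_femur,control,5,30,100,30
distal_femur,control,6,20,67,30
distal_femur,control,7,5,17,30
distal_femur,control,8,0,0,30
distal_femur,control,9,8,27,30
tibial_plateau,judo,1,15,50,30
tibial_plateau,judo,2,25,83,30
tibial_plateau,judo,3,18,60,30
tibial_plateau,judo,4,30,100,30
tibial_plateau,judo,5,23,77,30
tibial_plateau,judo,6,24,80,30
tibial_plateau,judo,7,28,93,30
tibial_plateau,judo,8,16,53,30
tibial_plateau,judo,9,0,0,30
tibial_plateau,control,1,7,23,30
tibial_plateau,control,2,19,63,30
tibial_plateau,control,3,10,33,30
tibial_plateau,control,4,20,67,30
tibial_plateau,control,5,16,53,30
tibial_plateau,control,6,13,43,30
tibial_plateau,control,7,15,50,30
tibial_plateau,control,8,9,30,30
tibial_plateau,control,9,0,0,30
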