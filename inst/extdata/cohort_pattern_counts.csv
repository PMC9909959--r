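bone,group,label,count,percent,n_knees
distal_femur,judo,Blank,0,0,30
distal_femur,judo,Anterior-Lateral,8,27,30
distal_femur,judo,Dual Center,19,63,30
distal_femur,judo,Center Connections,3,10,30
distal_femur,control,Blank,17,57,30
distal_femur,control,Anterior-Lateral,0,0,30
distal_femur,control,Dual Center,9,30,30
distal_femur,control,Center Connections,4,13,30
tibial_plateau,judo,Blank,0,0,30
tibial_plateau,judo,Scatter,17,57,30
tibial_plateau,judo,Multi-Center,5,17,30
tibial_plateau,judo,Multi-Center Connections,8,27,30
tibial_plateau,control,Blank,6,20,30
tibial_plateau,control,Scatter,16,53,30
tibial_plateau,control,Multi-Center,3,10,30
tibial_plateau,control,Multi-Center Connections,5,17,30
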