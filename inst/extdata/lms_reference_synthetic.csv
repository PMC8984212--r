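metric,sex,age_days,L,M,S
length_for_age,female,180,1,65.7,0.0352
length_for_age,female,270,1,70.1,0.0350
length_for_age,female,365,1,74.0,0.0349
length_for_age,female,456,1,77.1,0.0350
length_for_age,female,730,1,85.7,0.0354
length_for_age,male,180,1,67.6,0.0339
length_for_age,male,270,1,72.0,0.0337
length_for_age,male,365,1,75.7,0.0336
length_for_age,male,456,1,78.9,0.0337
length_for_age,male,730,1,87.1,0.0341
weight_for_age,female,180,-0.30,7.3,0.122
weight_for_age,female,270,-0.27,8.2,0.121
weight_for_age,female,365,-0.24,8.9,0.121
weight_for_age,female,456,-0.22,9.6,0.122
weight_for_age,female,730,-0.19,11.5,0.124
weight_for_age,male,180,0.05,7.9,0.110
weight_for_age,male,270,0.02,8.9,0.110
weight_for_age,male,365,-0.01,9.6,0.110
weight_for_age,male,456,-0.03,10.3,0.111
weight_for_age,male,730,-0.06,12.2,0.113
head_circumference,female,180,1,42.2,0.031
head_circumference,female,270,1,43.5,0.031
head_circumference,female,365,1,44.6,0.031
head_circumference,female,456,1,45.4,0.031
head_circumference,female,730,1,46.9,0.031
head_circumference,male,180,1,43.3,0.029
head_circumference,male,270,1,44.8,0.029
head_circumference,male,365,1,45.8,0.029
head_circumference,male,456,1,46.6,0.029
head_circumference,male,730,1,48.1,0.029
weight_for_length,female,65,-0.38,7.2,0.108
weight_for_length,female,75,-0.38,8.4,0.108
weight_for_length,female,85,-0.38,9.8,0.109
weight_for_length,female,95,-0.38,11.4,0.110
weight_for_length,male,65,-0.35,7.4,0.101
weight_for_length,male,75,-0.35,8.6,0.101
weight_for_length,male,85,-0.35,10.1,0.102
weight_for_length,male,95,-0.35,11.8,0.103
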