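variable,stratum,n,mean,sd,median,q1,q3
age,young,100,56.86,8.53,58.00,51.00,64.00
age,old,91,80.79,7.49,79.00,74.00,87.00
dbp,young,100,85.40,9.35,86.00,79.00,92.00
dbp,old,91,76.51,10.21,76.00,70.00,84.00
sbp,young,100,141.81,16.36,139.50,130.00,153.00
sbp,old,91,137.07,20.17,136.00,126.00,148.00
map,young,100,105.4,10.64,106.00,98.75,114.33
map,old,91,97.2,13.71,96.7,89.33,97.21
pp,young,100,54.9,13.18,53.00,46.75,60.00
pp,old,91,60.07,14.53,59.00,50.50,67.00
cavi0,young,100,11.49,2.64,10.91,9.58,13.44
cavi0,old,91,18.90,6.64,17.00,14.09,21.83
cavi,young,100,7.78,1.21,7.75,7.00,8.80
cavi,old,91,10.25,2.15,9.80,8.90,11.20
bmi,young,100,31.38,4.82,31.15,28.20,34.60
bmi,old,91,25.84,5.68,25.40,21.50,30.30
waist,young,100,103.6,13.88,103.00,94.25,113.75
waist,old,91,97.18,15.19,98.00,87.00,105.00
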