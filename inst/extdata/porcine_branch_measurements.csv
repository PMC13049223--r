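section,subject,label,infl,coll,diff,pct
diam,1,Trachea,16.85,13.84,-3.01,-17.9
diam,1,LMB,11.09,9.64,-1.45,-13.0
diam,1,LB1,5.47,4.17,-1.30,-23.7
diam,1,LB1Cr,2.29,2.11,-0.18,-7.8
diam,1,LB1Cd,4.57,4.04,-0.53,-11.6
diam,1,LB2,8.34,6.19,-2.15,-25.8
diam,1,LB3,5.60,3.02,-2.58,-46.1
diam,1,RMB,14.12,10.84,-3.28,-23.2
diam,1,RB1,4.79,2.74,-2.05,-42.8
diam,1,RB1Cr,3.38,2.37,-1.01,-29.9
diam,1,RB1Cd,2.98,2.95,-0.03,-1.0
diam,1,RB2,4.65,3.97,-0.68,-14.6
diam,1,RB3,3.17,2.59,-0.58,-18.4
diam,1,RB4,10.31,7.12,-3.19,-31.0
diam,1,RB5,2.64,1.98,-0.66,-24.8
diam,2,Trachea,16.84,14.82,-2,-12
diam,2,LMB,12.10,10.38,-1.7,-14
diam,2,LB1,5.56,3.67,-1.9,-34
diam,2,LB1Cr,2.94,2.02,-0.9,-31
diam,2,LB1Cd,3.65,2.35,-1.3,-36
diam,2,LB2,9.02,7.39,-1.6,-18
diam,2,LB3,3.34,3.19,-0.2,-5
diam,2,RMB,13.00,10.43,-2.6,-20
diam,2,RB1,4.19,3.20,-1,-24
diam,2,RB1Cr,3.33,3.25,-0.1,-2
diam,2,RB1Cd,3.34,1.57,-1.8,-53
diam,2,RB2,4.45,3.83,-0.6,-14
diam,2,RB3,3.05,2.72,-0.3,-11
diam,2,RB4,9.61,7.34,-2.3,-24
diam,2,RB5,2.78,2.20,-0.6,-21
len,1,Trachea,35.45,29.58,-5.87,-17
len,1,LMB,19.06,16.18,-2.88,-15
len,1,LB1,18.98,17.47,-1.52,-8
len,1,LB1Cr,10.21,8.90,-1.30,-13
len,1,LB1Cd,13.89,13.57,-0.32,-2
len,1,LB2,23.04,18.47,-4.57,-20
len,1,LB3,50.62,30.70,-19.91,-39
len,1,RMB,11.60,11.29,-0.31,-3
len,1,RB1,14.54,13.53,-1.01,-7
len,1,RB1Cr,9.73,7.37,-2.36,-24
len,1,RB1Cd,21.75,13.63,-8.12,-37
len,1,RB2,19.54,18.23,-1.30,-7
len,1,RB3,31.57,22.77,-8.80,-28
len,1,RB4,15.30,14.64,-0.66,-4
len,1,RB5,26.66,21.97,-4.69,-18
len,2,Trachea,37.00,35.77,-1.23,-3.3
len,2,LMB,20.51,18.03,-2.48,-12.1
len,2,LB1,16.11,17.52,1.41,8.8
len,2,LB1Cr,9.78,9.30,-0.48,-4.9
len,2,LB1Cd,71.24,58.22,-13.01,-18.3
len,2,LB2,18.53,20.99,2.46,13.3
len,2,LB3,28.15,43.06,14.91,53.0
len,2,RMB,13.91,14.04,0.13,0.9
len,2,RB1,13.37,15.77,2.40,18.0
len,2,RB1Cr,10.09,7.48,-2.62,-25.9
len,2,RB1Cd,32.99,9.98,-23.02,-69.8
len,2,RB2,16.81,16.36,-0.45,-2.7
len,2,RB3,16.67,18.16,1.49,9.0
len,2,RB4,15.16,16.80,1.64,10.8
len,2,RB5,18.67,60.60,41.92,224.5
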