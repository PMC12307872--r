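zone,side,x,y
B,upper,0,50
B,upper,30,50
B,upper,230,330
B,upper,440,550
C,upper,0,60
C,upper,30,60
C,upper,280,550
D,upper,0,80
D,upper,25,80
D,upper,35,90
D,upper,125,550
E,upper,0,200
E,upper,35,200
E,upper,50,550
B,lower,50,0
B,lower,90,0
B,lower,330,230
B,lower,550,450
C,lower,90,0
C,lower,260,130
C,lower,550,250
D,lower,250,0
D,lower,250,40
D,lower,410,110
D,lower,550,160
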