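# terminal state after 800 s pre-run; protocol: paced-1hz-750pA
state,value
Vm,-0.0730487559350387
Ca_SR,0.0709153733915938
Ca_i,1.44138291973633e-05
g_legacy,0
d,0.000107679385899831
f1,0.953490857978899
f2,0.999977504113818
fCa,0.99913703010717
Xr1,0.0220513351692913
Xr2,0.4258558012044
Xs,0.0349162104642173
h,0.749279815220632
j,0.191043260282287
m,0.110696154868722
Xf,0.0742701658459
q,0.82523189369179
r,0.00613939822740144
Na_i,6.74896703451679
mL,0.00321435270283217
hL,0.129296238438955
RyR_a,0.0372166169040229
RyR_o,1.49358856328587e-05
RyR_c,0.913911848391238
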