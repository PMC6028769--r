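# terminal state after 800 s pre-run; protocol: paced-1hz-550pA
state,value
Vm,-0.0731680430610829
Ca_SR,0.0735993787212751
Ca_i,1.46694960938673e-05
g_legacy,0
d,0.000105862826878147
f1,0.955548263126533
f2,0.999978163643019
fCa,0.999122189938243
Xr1,0.0202224803367852
Xr2,0.426438141707934
Xs,0.0346675060989371
h,0.752583956554658
j,0.195376905401003
m,0.109954661132555
Xf,0.0761115433773417
q,0.826541557020812
r,0.00610076788329536
Na_i,6.97181780602272
mL,0.00314265645510725
hL,0.131328514999766
RyR_a,0.0373772733171489
RyR_o,1.53925508308838e-05
RyR_c,0.914884588054179
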