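# terminal state after 800 s pre-run; protocol: spontaneous
state,value
Vm,-0.0593835515866428
Ca_SR,0.0946269121942391
Ca_i,1.81924514104163e-05
g_legacy,0
d,0.000732523254521069
f1,0.998313091382631
f2,0.999635927540758
fCa,0.998921028492504
Xr1,0.000629504448302009
Xr2,0.363570474546807
Xs,0.0663386436410582
h,0.486136119927161
j,0.314907133197768
m,0.238099914557847
Xf,0.114157248854861
q,0.684051711725429
r,0.0119782790081883
Na_i,8.65882861859848
mL,0.0411752892952851
hL,0.0767186364674078
RyR_a,0.0281349003183271
RyR_o,0.000979340691641591
RyR_c,0.994601370691252
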