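structure,metric,bound,units
Lens,Dmax,8,Gy
Eyes,Dmean,5,Gy
Parotids,V30,5,%
MandibularJoints,Dmax,70,Gy
Pituitary,Dmax,60,Gy
Mandibles,Dmax,70,Gy
Brainstem,Dmax,54,Gy
SpinalCord,Dmax,45,Gy
OpticNerves,Dmax,54,Gy
OpticChiasm,Dmax,54,Gy
TemporalLobes,Dmax,65,Gy
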