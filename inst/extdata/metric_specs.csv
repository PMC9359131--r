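structure,metric,category,direction,weight
PTVnx,TC,ptv,higher_better,1
PTVnd,TC,ptv,higher_better,1
PTV1,TC,ptv,higher_better,1
PTV2,TC,ptv,higher_better,1
PTVnx,CI,ptv,higher_better,1
PTVnd,CI,ptv,higher_better,1
PTV1,CI,ptv,higher_better,1
PTV2,CI,ptv,higher_better,1
PTVnx,HI,ptv,lower_better,1
PTVnd,HI,ptv,lower_better,1
PTV1,HI,ptv,lower_better,1
PTV2,HI,ptv,lower_better,1
PTVnx,D2,ptv,lower_better,1
PTVnd,D2,ptv,lower_better,1
PTV1,D2,ptv,lower_better,1
PTV2,D2,ptv,lower_better,1
TemporalLobes,Dmax,oar,lower_better,1
MandibularJoints,Dmax,oar,lower_better,1
Mandibles,Dmax,oar,lower_better,1
SpinalCord,Dmax,oar,lower_better,1
OpticNerves,Dmax,oar,lower_better,1
OpticChiasm,Dmax,oar,lower_better,1
Brainstem,Dmax,oar,lower_better,1
Parotids,V30,oar,lower_better,1
Pituitary,Dmax,oar,lower_better,1
Lens,Dmax,oar,lower_better,1
Eyes,Dmean,oar,lower_better,1
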