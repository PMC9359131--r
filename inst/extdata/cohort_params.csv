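group,structure,metric,category,mean,sd
BL02,PTVnx,CI,ptv,0.62,0.05
BL04,PTVnx,CI,ptv,0.62,0.04
BL06,PTVnx,CI,ptv,0.62,0.04
BL08,PTVnx,CI,ptv,0.61,0.05
BL10,PTVnx,CI,ptv,0.59,0.05
BL02,PTVnd,CI,ptv,0.14,0.07
BL04,PTVnd,CI,ptv,0.15,0.08
BL06,PTVnd,CI,ptv,0.15,0.08
BL08,PTVnd,CI,ptv,0.14,0.07
BL10,PTVnd,CI,ptv,0.14,0.07
BL02,PTV1,CI,ptv,0.47,0.08
BL04,PTV1,CI,ptv,0.48,0.08
BL06,PTV1,CI,ptv,0.48,0.08
BL08,PTV1,CI,ptv,0.47,0.07
BL10,PTV1,CI,ptv,0.47,0.08
BL02,PTV2,CI,ptv,0.76,0.05
BL04,PTV2,CI,ptv,0.77,0.05
BL06,PTV2,CI,ptv,0.77,0.05
BL08,PTV2,CI,ptv,0.75,0.05
BL10,PTV2,CI,ptv,0.76,0.05
BL02,PTVnx,HI,ptv,0.07,0.02
BL04,PTVnx,HI,ptv,0.07,0.02
BL06,PTVnx,HI,ptv,0.07,0.02
BL08,PTVnx,HI,ptv,0.08,0.02
BL10,PTVnx,HI,ptv,0.08,0.02
BL02,PTVnd,HI,ptv,0.07,0.01
BL04,PTVnd,HI,ptv,0.07,0.01
BL06,PTVnd,HI,ptv,0.08,0.01
BL08,PTVnd,HI,ptv,0.08,0.01
BL10,PTVnd,HI,ptv,0.09,0.01
BL02,PTV1,HI,ptv,0.15,0.02
BL04,PTV1,HI,ptv,0.14,0.01
BL06,PTV1,HI,ptv,0.15,0.01
BL08,PTV1,HI,ptv,0.16,0.02
BL10,PTV1,HI,ptv,0.15,0.03
BL02,PTV2,HI,ptv,0.27,0.02
BL04,PTV2,HI,ptv,0.27,0.02
BL06,PTV2,HI,ptv,0.28,0.02
BL08,PTV2,HI,ptv,0.29,0.02
BL10,PTV2,HI,ptv,0.29,0.03
BL02,PTVnx,TC,ptv,98.04,1.2
BL04,PTVnx,TC,ptv,98.16,1.10
BL06,PTVnx,TC,ptv,97.92,1.16
BL08,PTVnx,TC,ptv,97.60,1.09
BL10,PTVnx,TC,ptv,97.50,1.10
BL02,PTVnd,TC,ptv,98.25,1.16
BL04,PTVnd,TC,ptv,98.31,1.23
BL06,PTVnd,TC,ptv,97.82,0.90
BL08,PTVnd,TC,ptv,97.49,0.86
BL10,PTVnd,TC,ptv,96.96,0.93
BL02,PTV1,TC,ptv,98.23,0.84
BL04,PTV1,TC,ptv,98.30,0.80
BL06,PTV1,TC,ptv,98.00,0.71
BL08,PTV1,TC,ptv,97.84,0.61
BL10,PTV1,TC,ptv,97.59,0.61
BL02,PTV2,TC,ptv,98.01,1.05
BL04,PTV2,TC,ptv,98.15,1.01
BL06,PTV2,TC,ptv,97.76,0.92
BL08,PTV2,TC,ptv,97.40,0.75
BL10,PTV2,TC,ptv,97.16,0.42
BL02,PTVnx,D2,ptv,74.56,0.33
BL04,PTVnx,D2,ptv,74.55,0.27
BL06,PTVnx,D2,ptv,74.72,0.32
BL08,PTVnx,D2,ptv,75.05,0.54
BL10,PTVnx,D2,ptv,75.15,0.58
BL02,PTVnd,D2,ptv,70.96,0.30
BL04,PTVnd,D2,ptv,71.01,0.28
BL06,PTVnd,D2,ptv,71.00,0.26
BL08,PTVnd,D2,ptv,71.01,0.22
BL10,PTVnd,D2,ptv,71.09,0.20
BL02,PTV1,D2,ptv,74.26,0.34
BL04,PTV1,D2,ptv,74.27,0.30
BL06,PTV1,D2,ptv,74.40,0.35
BL08,PTV1,D2,ptv,74.70,0.56
BL10,PTV1,D2,ptv,74.59,1.05
BL02,PTV2,D2,ptv,73.48,0.43
BL04,PTV2,D2,ptv,73.49,0.40
BL06,PTV2,D2,ptv,73.56,0.44
BL08,PTV2,D2,ptv,73.79,0.57
BL10,PTV2,D2,ptv,73.89,0.64
BL02,TemporalLobes,Dmax,oar,72.39,3.63
BL04,TemporalLobes,Dmax,oar,71.91,4.03
BL06,TemporalLobes,Dmax,oar,72.28,3.84
BL08,TemporalLobes,Dmax,oar,73.03,4.03
BL10,TemporalLobes,Dmax,oar,73.03,4.03
BL02,MandibularJoints,Dmax,oar,66.29,5.30
BL04,MandibularJoints,Dmax,oar,66.27,5.56
BL06,MandibularJoints,Dmax,oar,66.03,5.89
BL08,MandibularJoints,Dmax,oar,67.29,5.68
BL10,MandibularJoints,Dmax,oar,66.56,5.18
BL02,Mandibles,Dmax,oar,68.02,3.97
BL04,Mandibles,Dmax,oar,68.06,4.13
BL06,Mandibles,Dmax,oar,67.74,4.38
BL08,Mandibles,Dmax,oar,67.40,3.70
BL10,Mandibles,Dmax,oar,67.77,3.95
BL02,SpinalCord,Dmax,oar,42.87,1.33
BL04,SpinalCord,Dmax,oar,43.18,3.06
BL06,SpinalCord,Dmax,oar,42.89,1.71
BL08,SpinalCord,Dmax,oar,43.07,1.33
BL10,SpinalCord,Dmax,oar,43.49,1.23
BL02,OpticNerves,Dmax,oar,40.25,16.24
BL04,OpticNerves,Dmax,oar,41.35,16.34
BL06,OpticNerves,Dmax,oar,42.48,15.5
BL08,OpticNerves,Dmax,oar,44.77,14.38
BL10,OpticNerves,Dmax,oar,43.28,13.75
BL02,OpticChiasm,Dmax,oar,38.03,17.16
BL04,OpticChiasm,Dmax,oar,39.06,17.30
BL06,OpticChiasm,Dmax,oar,41.96,14.46
BL08,OpticChiasm,Dmax,oar,43.08,14.81
BL10,OpticChiasm,Dmax,oar,40.61,13.38
BL02,Brainstem,Dmax,oar,49.18,2.25
BL04,Brainstem,Dmax,oar,49.10,2.22
BL06,Brainstem,Dmax,oar,49.19,2.48
BL08,Brainstem,Dmax,oar,49.50,2.51
BL10,Brainstem,Dmax,oar,50.90,4.65
BL02,Parotids,V30,oar,49.01,6.73
BL04,Parotids,V30,oar,48.51,5.54
BL06,Parotids,V30,oar,48.86,6.17
BL08,Parotids,V30,oar,51.3,7.68
BL10,Parotids,V30,oar,53.53,10.11
BL02,Pituitary,Dmax,oar,55.16,11.25
BL04,Pituitary,Dmax,oar,52.88,11.54
BL06,Pituitary,Dmax,oar,55.97,8.60
BL08,Pituitary,Dmax,oar,55.68,9.73
BL10,Pituitary,Dmax,oar,55.26,9.53
BL02,Lens,Dmax,oar,7.53,2.33
BL04,Lens,Dmax,oar,7.27,2.19
BL06,Lens,Dmax,oar,7.24,2.14
BL08,Lens,Dmax,oar,7.28,2.16
BL10,Lens,Dmax,oar,7.31,2.24
BL02,Eyes,Dmean,oar,7.61,2.39
BL04,Eyes,Dmean,oar,7.52,2.37
BL06,Eyes,Dmean,oar,7.78,2.28
BL08,Eyes,Dmean,oar,7.88,2.32
BL10,Eyes,Dmean,oar,7.98,2.29
BL02,Plan,MU,efficiency,739.80,43.74
BL04,Plan,MU,efficiency,843.03,52.62
BL06,Plan,MU,efficiency,776.97,30.51
BL08,Plan,MU,efficiency,728.17,42.41
BL10,Plan,MU,efficiency,701.71,30.67
BL02,Plan,SmallSegPct,efficiency,32.35,6.27
BL04,Plan,SmallSegPct,efficiency,15.70,7.67
BL06,Plan,SmallSegPct,efficiency,24.10,6.41
BL08,Plan,SmallSegPct,efficiency,32.75,6.32
BL10,Plan,SmallSegPct,efficiency,39.50,5.89
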