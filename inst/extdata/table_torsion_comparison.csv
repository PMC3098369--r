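structure,dp,type,torsion,value,abs_printed
CN6 (NMR/simulation),6,b14,phi,-73,NA
CN6 (NMR/simulation),6,b14,psi,-117,NA
CN6 (NMR/simulation),6,b13,phi,-72,NA
CN6 (NMR/simulation),6,b13,psi,108,NA
CS5 (NMR/simulation),5,b14,phi,-67,6
CS5 (NMR/simulation),5,b14,psi,-124,7
CS5 (NMR/simulation),5,b13,phi,-61,11
CS5 (NMR/simulation),5,b13,psi,109,1
CS (X-ray fibre),4,b14,phi,-98,25
CS (X-ray fibre),4,b14,psi,-174,57
CS (X-ray fibre),4,b13,phi,-80,8
CS (X-ray fibre),4,b13,psi,107,1
CS2 (X-ray chondroitinase B),2,b14,phi,-69,4
CS2 (X-ray chondroitinase B),2,b14,psi,-180,63
CS2 (X-ray chondroitinase B),2,b13,phi,-89,17
CS2 (X-ray chondroitinase B),2,b13,psi,108,0
CS2 (simulation MM3),2,b14,phi,-79,6
CS2 (simulation MM3),2,b14,psi,-111,6
CS2 (simulation MM3),2,b13,phi,-79,7
CS2 (simulation MM3),2,b13,psi,90,18
CN4 (simulation CHARMM),4,b14,phi,-70,3
CN4 (simulation CHARMM),4,b14,psi,-120,3
CN4 (simulation CHARMM),4,b13,phi,-70,2
CN4 (simulation CHARMM),4,b13,psi,90,18
CS8 (NMR/simulation),8,b14,phi,-80,7
CS8 (NMR/simulation),8,b14,psi,-110,7
CS8 (NMR/simulation),8,b13,phi,-80,8
CS8 (NMR/simulation),8,b13,psi,90,18
HA8 (NMR),8,b14,phi,-71,4
HA8 (NMR),8,b14,psi,-116,7
HA8 (NMR),8,b13,phi,-68,8
HA8 (NMR),8,b13,psi,129,20
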