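linkage,type,donor_label,acceptor_label,phi_mean,phi_sd,psi_mean,psi_sd
1,b13,U2,N1,-73,2,108,8
2,b14,N3,U2,-73,0,-118,1
3,b13,U4,N3,-73,0,107,0
4,b14,N5,U4,-73,0,-116,0
5,b13,U6,N5,-72,0,109,0
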