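name,K_N,L0_mm,eps_r,eps_l,damping_c,group,active
aACL,3600,32,0.03,0.03,0.5,ACL,TRUE
pACL,4000,34,0.03,0.03,0.5,ACL,TRUE
aPCL,4000,34,-0.05,0.03,0.5,PCL,TRUE
pPCL,1600,32,-0.06,0.03,0.5,PCL,TRUE
aMCL,2000,85,0.02,0.03,0.5,MCL,TRUE
iMCL,2000,85,0.03,0.03,0.5,MCL,TRUE
pMCL,4000,56,0.05,0.03,0.5,MCL,TRUE
aDMCL,2000,58,0.02,0.03,0.5,DMCL,TRUE
pDMCL,1800,57,0.05,0.03,0.5,DMCL,TRUE
LCL,3400,49,0.05,0.03,0.5,LCL,TRUE
POPL,1900,45,-0.05,0.03,0.5,POPL,TRUE
ALL,2700,43,0.05,0.03,0.5,ALL,TRUE
CAPa,1350,45,0.05,0.03,0.5,CAP,TRUE
CAPo,1500,43,0.05,0.03,0.5,CAP,TRUE
CAPm,2000,28,0.05,0.03,0.5,CAP,TRUE
CAPl,2000,27,0.05,0.03,0.5,CAP,TRUE
cPT,6000,48,0.01,0.03,0.5,PT,FALSE
mPT,6000,47,0.01,0.03,0.5,PT,FALSE
lPT,6000,45,0.01,0.03,0.5,PT,FALSE
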