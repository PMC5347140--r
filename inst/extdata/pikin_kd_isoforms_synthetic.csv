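compound,isoform,kd_nM
PIKiN1,p110alpha,15
PIKiN1,p110beta,40
PIKiN1,p110gamma,25
PIKiN1,p110delta,10
PIKiN1-R1,p110alpha,170
PIKiN1-R1,p110beta,400
PIKiN1-R1,p110gamma,210
PIKiN1-R1,p110delta,300
PIKiN2,p110alpha,5
PIKiN2,p110beta,20
PIKiN2,p110gamma,12
PIKiN2,p110delta,6
PIKiN2-R1,p110alpha,60
PIKiN2-R1,p110beta,150
PIKiN2-R1,p110gamma,190
PIKiN2-R1,p110delta,100
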