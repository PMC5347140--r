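cell_line,ic50_uM
CL01,0.12
CL02,0.18
CL03,0.25
CL04,0.32
CL05,0.40
CL06,0.48
CL07,0.55
CL08,0.63
CL09,0.70
CL10,0.78
CL11,0.85
CL12,0.90
CL13,0.95
CL14,0.98
CL15,1.02
CL16,1.05
CL17,1.08
CL18,1.10
CL19,1.12
CL20,1.15
CL21,1.17
CL22,1.19
CL23,1.21
CL24,1.25
CL25,1.30
CL26,1.38
CL27,1.45
CL28,1.55
CL29,1.68
CL30,1.80
CL31,1.95
CL32,2.10
CL33,2.30
CL34,2.55
CL35,2.80
CL36,3.10
CL37,3.50
CL38,4.00
CL39,4.60
CL40,5.30
CL41,6.20
CL42,7.50
CL43,9.00
CL44,12.10
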