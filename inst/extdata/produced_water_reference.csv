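sample,pred1,pred2,lcms,difference
S01,4.89,97.80,84.48,13.32
S02,12.09,241.80,209.52,32.28
S03,3.12,62.40,61.50,0.90
S04,16.02,320.40,308.61,11.79
S05,8.19,163.80,158.73,5.07
S06,1.56,31.20,28.28,2.92
S07,2.03,40.60,35.75,4.85
S08,1.98,39.60,35.28,4.32
S09,1.87,37.40,35.8,1.60
S10,9.47,189.40,165.6,23.8
S11,2.09,41.80,35.64,6.16
S12,3.49,69.80,62.28,7.52
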