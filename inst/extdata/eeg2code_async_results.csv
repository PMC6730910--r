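subject,clm,acc,itr,time_s,utr
S10,33.3,99.0,165.4,1.77,165.0
S11,48.2,97.9,238.9,1.19,238.8
S12,39.7,99.5,197.8,1.49,196.8
S13,28.7,99.5,142.8,2.07,142.1
S14,35.8,95.3,177.8,1.52,177.6
S15,30.7,99.0,152.4,1.92,152.0
S16,45.1,100.0,225.3,1.33,223.2
S17,25.8,97.4,127.8,2.21,127.7
S18,30.9,100.0,154.4,1.94,153.0
S19,34.8,97.4,172.3,1.64,172.2
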