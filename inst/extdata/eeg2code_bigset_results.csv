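subject,acc_ridge,itr_ridge,acc_cnn,itr_cnn
S01,96.3,431.8,100.0,454.3
S02,55.4,227.7,82.1,357.0
S03,42.0,167.1,79.9,345.7
S04,76.8,330.1,97.8,440.5
S05,71.9,306.0,96.9,435.3
S06,84.4,368.4,95.5,427.8
S07,53.1,217.4,52.7,215.4
S08,8.0,26.8,93.8,417.9
S09,6.3,20.3,57.1,236.0
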