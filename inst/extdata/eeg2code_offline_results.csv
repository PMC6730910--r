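subject,pattern_acc_ridge,pattern_itr_ridge,pattern_acc_cnn,pattern_itr_cnn,sync_acc_ridge,sync_itr_ridge,sync_acc_cnn,sync_itr_cnn
S01,69.1,389.9,83.4,1262.1,99.2,195.8,100.0,200.0
S02,64.5,222.4,72.9,567.3,94.1,175.5,94.6,177.3
S03,63.7,196.5,72.5,545.7,83.4,141.2,95.5,180.6
S04,65.6,257.8,76.8,787.9,95.9,182.1,98.7,193.2
S05,66.3,282.7,78.7,908.9,96.4,183.8,99.6,197.5
S06,67.1,308.2,75.4,704.9,98.1,191.0,98.7,193.2
S07,63.7,196.8,68.5,363.9,88.4,156.4,87.9,154.9
S08,60.9,124.5,77.1,807.1,65.6,94.6,99.6,197.5
S09,60.2,109.4,68.5,363.7,53.5,68.0,87.5,153.5
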