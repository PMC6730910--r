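quantity,value
mean_run_acc_pct,83.4
best_run_acc_pct,92.6
bits_per_run,285
run_seconds,5
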