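{"n_plates":20,"wells_per_plate":96,"seed_cells_per_well":500,"expansion_target_cells":20000,"T_treat":14,"T_obs":84,"early_cutoff_days":28,"late_cutoff_days":70,"colony_detection_threshold":50,"persister_read_day":21,".class":"experiment_design"}
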