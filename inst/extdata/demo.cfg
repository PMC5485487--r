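# sipcall demo configuration: simulated SIP experiment, full pipeline.
# 20 taxa, 2 of them fully 13C-labeled; 2 labeled bottles + 1 control.
sim.n_taxa = 20
sim.n_labeled = 2
sim.depth = 10000
sim.n_label_replicates = 2
seed = 1
boot = 200
light_max = 1.715
heavy_min = 1.72
min_reads = 5
roor_threshold = 1.0
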