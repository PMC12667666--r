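# Demonstration-scale fully synthetic run (see ?defaultConfig for all keys).
seed = 1
n_trnas = 12
n_modified_both = 5
n_modified_oe_only = 2
reads_per_library = 8000
replicates_per_condition = 2
conditions = vector, WDR4_OE
min_coverage = 50
min_stop_fraction = 0.10
alpha = 0.01
te_n_genes = 600
te_depth = 2e5
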