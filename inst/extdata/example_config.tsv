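# repairprime example run configuration (synthetic, desk-scale)
seed	11
n_chroms	2
chrom_length	400000
n_genes	60
n_repair_reads	10000
n_primed	8
n_up	8
n_down	12
n_peaks	40
n_fragments	8000
n_false_peaks	4
theta_sensitive	0.5
theta_resistant	0.8
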