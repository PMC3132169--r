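term	proportion
binding	0.40
catalytic_activity	0.35
metabolic_process	0.10
cellular_process	0.08
localization	0.04
cell_part	0.03
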