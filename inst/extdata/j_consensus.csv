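"chain_class","fr4","source_tag"
"heavy","WGQGTLVTVSS","curated J-segment consensus"
"kappa","FGQGTKVEIK","curated J-segment consensus"
"lambda","FGGGTKLTVL","curated J-segment consensus"
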