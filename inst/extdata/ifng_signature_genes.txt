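# Interferon-gamma 6-gene comparator signature (Ayers et al.-style
# preliminary IFN-gamma set); editable, one symbol per line.
IFNG
STAT1
IDO1
CXCL9
CXCL10
HLA-DRA
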