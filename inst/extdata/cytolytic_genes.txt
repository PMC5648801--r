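# Cytolytic-activity comparator signature (geometric-mean pair used as a
# simple mean here); editable, one symbol per line.
GZMA
PRF1
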