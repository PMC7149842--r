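# Known Klippel-Feil syndrome genes
GDF6
MEOX1
GDF3
MYO18B
RIPPLY2
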