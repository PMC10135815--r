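>PLD FUS_HUMAN (UniProt P35637) residues 1-50, prion-like domain N-terminal segment
MASNDYTQQATQSYGAYPTQPGQGYSQQSSQPYGQQSYSGYSQSTDTSGY
>RGG FUS_HUMAN (UniProt P35637) residues 453-502, RGG3 segment
DGPGGGPGGSHMGGNYGDDRRGGRGGYDRGGYRGRGGDRGGFRGGRGGGD
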