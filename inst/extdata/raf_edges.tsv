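parent	child
Plcg	PIP2
Plcg	PIP3
PIP3	PIP2
PIP3	Akt
PIP2	PKC
PKC	Mek
PKC	Raf
PKC	PKA
PKC	Jnk
PKC	P38
PKA	Raf
PKA	Mek
PKA	Erk
PKA	Akt
PKA	Jnk
PKA	P38
Raf	Mek
Mek	Erk
Erk	Akt
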