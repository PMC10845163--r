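# Three-gene repression ring with a self-sustaining input
targets, factors
lacI, !tetR
tetR, !cI
cI, !lacI & (cI | tetR)
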