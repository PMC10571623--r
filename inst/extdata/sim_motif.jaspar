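>sim_motif
A [ 1 18 1 1 18 1 1 1 18 1 ]
C [ 0.5 1.0 0.5 0.5 1.0 18.0 0.5 18.0 1.0 0.5 ]
G [ 18.0 0.5 0.5 0.5 0.5 0.5 18.0 0.5 0.5 0.5 ]
T [ 0.5 0.5 18.0 18.0 0.5 0.5 0.5 0.5 0.5 18.0 ]
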