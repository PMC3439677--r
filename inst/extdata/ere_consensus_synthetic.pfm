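>ERE_consensus_synthetic GGTCAnnnTGACC
A [  0  0  0  0 10  0  0  0  0  0 10  0  0 ]
C [  0  0  0 10  0  0  0  0  0  0  0 10 10 ]
G [ 10 10  0  0  0  0  0  0  0 10  0  0  0 ]
T [  0  0 10  0  0  0  0  0 10  0  0  0  0 ]
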