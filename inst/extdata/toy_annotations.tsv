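A	cytoskeleton,transport
B	cytoskeleton
C	cytoskeleton,signaling
D	signaling
E	signaling,transport
F	signaling
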