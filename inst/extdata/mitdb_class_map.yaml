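# Beat-symbol -> class-id map used when reading annotated WFDB records.
# Eight classes: the normal beat plus seven pathological morphologies.
# Edit freely: any symbol absent from this map is dropped at read time.
"N": 1   # normal
"L": 2   # left bundle branch block
"R": 3   # right bundle branch block
"V": 4   # premature ventricular contraction
"A": 5   # atrial premature
"F": 6   # fusion of ventricular and normal
"/": 7   # paced
"E": 8   # ventricular escape
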