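patient_id,eligible
p001,Y
p002,N
p003,N
p004,Y
p005,N
p006,Y
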