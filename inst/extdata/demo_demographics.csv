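patient_id,age,gender
p001,45,F
p002,31,W
p003,28,female
p004,52,M
p005,36,F
p006,67,male
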