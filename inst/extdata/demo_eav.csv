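patient_id,code,system
p001,L40.4,diagnosis
p001,5-121.1,procedure
p002,L41.0,diagnosis
p002,O82,diagnosis
p003,O09.6,diagnosis
p003,5-749.0,procedure
p004,L40.4,diagnosis
p004,L40.4,diagnosis
p005,Z37.0,diagnosis
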