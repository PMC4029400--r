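system,range_start,range_end,label
diagnosis,L40,L45,Papulosquamous disorders
diagnosis,O20,O29,Other maternal disorders predominantly related to pregnancy
diagnosis,O85,O99,Other obstetric conditions not elsewhere classified
procedure,5-08,5-16,Eye surgery
procedure,5-72,5-75,Obstetric procedures
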