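xl_type,term,name,eq_value,force_constant,note
HLKNL,bond,PRO1-AMN,0.365,7000,synthetic supplementary-derived stand-in; overridable
HLKNL,bond,AMN-KET1,0.360,7000,synthetic supplementary-derived stand-in; overridable
HLKNL,angle,PRO1-AMN-KET1,155,100,synthetic supplementary-derived stand-in; overridable
PYD,bond,R1-R2,0.255,25000,synthetic supplementary-derived stand-in; overridable
PYD,bond,R1-R3,0.250,25000,synthetic supplementary-derived stand-in; overridable
PYD,bond,R2-R4,0.250,25000,synthetic supplementary-derived stand-in; overridable
PYD,bond,R3-R4,0.255,25000,synthetic supplementary-derived stand-in; overridable
PYD,bond,R1-LNK,0.310,9000,synthetic supplementary-derived stand-in; overridable
PYD,bond,R3-CA3,0.305,9000,synthetic supplementary-derived stand-in; overridable
PYD,angle,R2-R1-LNK,130,120,synthetic supplementary-derived stand-in; overridable
PYD,angle,R3-R1-LNK,125,120,synthetic supplementary-derived stand-in; overridable
PYD,angle,R1-R3-CA3,128,120,synthetic supplementary-derived stand-in; overridable
PYD,angle,R4-R3-CA3,122,120,synthetic supplementary-derived stand-in; overridable
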