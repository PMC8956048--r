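sample,reference,predicted
S16,YN,YN
S19,YN,YN
S22,YN,YN
S25,YN,YN
S35,YN,YN
S50,YN,YN
S57,DBM,DBM
S64,DBM,DBM
S65,DBM,DBM
S67,DBM,DBM
S68,DBM,DBM
S69,DBM,DBM
S73,DBM,DBM
S76,DBM,DBM
S80,DBM,DBM
S83,XQ,XQ
S88,XQ,XQ
S92,XQ,DBM
S93,DBM,DBM
S101,DBM,DBM
S102,DBM,DBM
S109,DBM,DBM
S112,DBM,DBM
S121,YN,YN
S128,DBM,DBM
S133,YN,YN
S136,XQ,DBM
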