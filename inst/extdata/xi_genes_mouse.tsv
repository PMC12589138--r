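gene	category
Xist	xi
Tsix	xi
Kdm6a	xi
Kdm5c	xi
Ddx3x	xi
Eif2s3x	xi
Utx	xi
Jarid1c	xi
Uba1	xi
Pgk1	xi
Ddx3y	chrY
Eif2s3y	chrY
Uty	chrY
Kdm5d	chrY
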