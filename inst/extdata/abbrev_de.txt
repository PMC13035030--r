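Dr.
Prof.
Nr.
St.
Hr.
Fr.
bzw.
ca.
evtl.
ggf.
inkl.
u.a.
usw.
vgl.
z.B.
d.h.
Mio.
Mrd.
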