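a
ad
al
alla
alle
anche
che
chi
ci
come
con
cui
da
dal
della
delle
di
e
è
ed
gli
ha
hanno
i
il
in
la
le
lo
loro
ma
ne
nel
nella
noi
non
o
per
più
quella
quello
questa
questo
se
si
sono
su
tra
un
una
uno
voi
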