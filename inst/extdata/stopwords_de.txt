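aber
alle
als
also
am
an
auch
auf
aus
bei
bin
bis
bist
da
damit
dann
das
dass
dem
den
der
des
dessen
die
dies
diese
diesem
diesen
dieser
dieses
doch
dort
du
durch
ein
eine
einem
einen
einer
eines
er
es
etwas
für
gegen
hab
habe
haben
hat
hatte
hatten
hier
ich
ihr
ihre
im
in
ist
ja
kann
kein
keine
können
man
mehr
mein
mit
nach
nicht
noch
nun
nur
ob
oder
ohne
schon
sehr
sein
seine
sich
sie
sind
so
soll
sollen
um
und
uns
unser
vom
von
vor
war
waren
was
wenn
werden
wie
wieder
wir
wird
wurde
wurden
zu
zum
zur
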