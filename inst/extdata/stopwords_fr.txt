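au
aux
avec
ce
ces
cette
dans
de
des
du
elle
en
et
est
il
ils
je
la
le
les
leur
lui
mais
me
même
ne
nos
notre
nous
on
ou
où
par
pas
pour
que
qui
sa
se
ses
son
sont
sur
tout
tu
un
une
vos
votre
vous
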