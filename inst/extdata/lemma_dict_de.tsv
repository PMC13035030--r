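fehlinformationen	fehlinformation
desinformationen	desinformation
falschinformationen	falschinformation
verschwörungstheorien	verschwörungstheorie
verschwörungstheoretiker	verschwörungstheoretiker
impfungen	impfung
massnahmen	massnahme
maßnahmen	massnahme
medien	medium
lügen	lüge
mythen	mythos
pandemien	pandemie
epidemien	epidemie
seuchen	seuche
viren	virus
theorien	theorie
regierungen	regierung
staaten	staat
verbreitet	verbreiten
verbreiten	verbreiten
verbreitete	verbreiten
entkräftet	entkräften
widerlegt	widerlegen
geimpft	impfen
ungeimpft	ungeimpft
journalisten	journalist
journalistinnen	journalistin
politiker	politiker
politikerinnen	politikerin
institutionen	institution
plattformen	plattform
debatten	debatte
diskussionen	diskussion
narrative	narrativ
fakten	faktum
faktenchecks	faktencheck
zeitungen	zeitung
artikel	artikel
berichte	bericht
quellen	quelle
kampagnen	kampagne
krisen	krise
ängste	angst
gefahren	gefahr
folgen	folge
studien	studie
zahlen	zahl
statistiken	statistik
einschränkungen	einschränkung
hospitalisierungen	hospitalisierung
grundrechte	grundrecht
bewegungen	bewegung
menschen	mensch
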