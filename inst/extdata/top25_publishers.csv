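rank,host,cctld,publisher_type
1,www.rki.de,.de,PI
2,www.aerzteblatt.de,.de,PI
3,www.charite.de,.de,PI
4,www.deutsche-alzheimer.de,.de,NPO
5,www.aerztezeitung.de,.de,PO
6,www.dge.de,.de,NPO
7,www.g-ba.de,.de,PI
8,www.bzga.de,.de,PI
9,www.bundesgesundheitsministerium.de,.de,PI
10,www.apotheken-umschau.de,.de,PO
11,www.dimdi.de,.de,PI
12,www.gesundheitsinformation.de,.de,PI
13,www.osteopathie.de,.de,NPO
14,www.krebsgesellschaft.de,.de,NPO
15,www.bfarm.de,.de,PI
16,www.kbv.de,.de,PI
17,www.krebshilfe.de,.de,NPO
18,www.tk.de,.de,PO
19,www.ebm-netzwerk.de,.de,NPO
20,www.bmg.bund.de,.de,PI
21,www.netdoktor.de,.de,PO
22,www.drk.de,.de,NPO
23,www.herzstiftung.de,.de,NPO
24,www.klinikum.uni-heidelberg.de,.de,PI
25,www.aok.de,.de,PO
1,www.gesundheit.gv.at,.at,PI
2,www.meduniwien.ac.at,.at,PI
3,www.bmgf.gv.at,.at,PI
4,www.sozialministerium.at,.at,PI
5,www.apotheker.or.at,.at,PI
6,www.sam-pharma.at,.at,PO
7,www.aerztekammer.at,.at,PI
8,www.univie.ac.at,.at,PI
9,www.herz-ambulatorium.at,.at,PO
10,www.herz-ordination.at,.at,PO
11,www.tg-steiermark.at,.at,NPO
12,www.impuls-fs.at,.at,PO
13,www.medunigraz.at,.at,PI
14,www.brustvergroesserung-leicht.at,.at,PO
15,www.bmg.gv.at,.at,PI
16,www.kages.at,.at,PO
17,science.orf.at,.at,PI
18,www.gynmed.at,.at,PO
19,www.fhstp.ac.at,.at,PI
20,www.dr-boehm.at,.at,PO
21,bmg.gv.at,.at,PI
22,www.novartis.at,.at,PO
23,www.babyforum.at,.at,PO
24,femmestyle.at,.at,PO
25,www.pfizer.at,.at,PO
1,www.uzh.ch,.ch,PI
2,www.usz.ch,.ch,PI
3,www.srf.ch,.ch,PI
4,www.netdoktor.ch,.ch,PO
5,www.pancreas-help.ch,.ch,NPO
6,www.mutterglueck.ch,.ch,PO
7,www.association-osteo-swiss.ch,.ch,NPO
8,www.unibas.ch,.ch,PI
9,www.ethz.ch,.ch,PI
10,www.rheumaliga.ch,.ch,NPO
11,www.lungenliga.ch,.ch,NPO
12,www.rotpunkt-apotheken.ch,.ch,PO
13,www.pharmawiki.ch,.ch,PO
14,www.bayer.ch,.ch,PO
15,www.patientensicherheit.ch,.ch,NPO
16,saez.ch,.ch,NPO
17,www.swissheart.ch,.ch,NPO
18,gesundheitsfoerderung.ch,.ch,NPO
19,sensomotorische-lebensweisen.ch,.ch,PO
20,www.spitaluster.ch,.ch,PO
21,symptome.ch,.ch,PO
22,www.meineimpfungen.ch,.ch,NPO
23,unicef.ch,.ch,NPO
24,www.bauchtumor.ch,.ch,PI
25,www.fettabsaugungen.ch,.ch,PO
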