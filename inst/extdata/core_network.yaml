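metabolites:
- id: glc
  carbons: 6
  boundary: yes
- id: pyr.ext
  carbons: 3
  boundary: yes
- id: lac.ext
  carbons: 3
  boundary: yes
- id: co2
  carbons: 1
  boundary: yes
- id: oaa.in
  carbons: 4
  boundary: yes
- id: pg3
  carbons: 3
  boundary: no
- id: pyr
  carbons: 3
  boundary: no
- id: lac
  carbons: 3
  boundary: no
- id: ala
  carbons: 3
  boundary: no
- id: ser
  carbons: 3
  boundary: no
- id: accoa
  carbons: 2
  boundary: no
- id: oaa
  carbons: 4
  boundary: no
- id: cit
  carbons: 6
  boundary: no
- id: akg
  carbons: 5
  boundary: no
- id: suc
  carbons: 4
  boundary: no
- id: fum
  carbons: 4
  boundary: no
- id: mal
  carbons: 4
  boundary: no
- id: asp
  carbons: 4
  boundary: no
- id: glu
  carbons: 5
  boundary: no
- id: pro
  carbons: 5
  boundary: no
- id: pyr.out
  carbons: 3
  boundary: yes
- id: lac.out
  carbons: 3
  boundary: yes
- id: ala.out
  carbons: 3
  boundary: yes
- id: ser.out
  carbons: 3
  boundary: yes
- id: asp.out
  carbons: 4
  boundary: yes
- id: glu.out
  carbons: 5
  boundary: yes
- id: pro.out
  carbons: 5
  boundary: yes
- id: cit.out
  carbons: 6
  boundary: yes
- id: oaa.out
  carbons: 4
  boundary: yes
reactions:
- id: glyc
  equation: glc -> pg3 + pg3
  map: abcdef -> cba + def
- id: pk
  equation: pg3 -> pyr
  map: abc -> abc
- id: ser_syn
  equation: pg3 -> ser
  map: abc -> abc
- id: ser_out
  equation: ser -> ser.out
  map: abc -> abc
- id: ldh_f
  equation: pyr -> lac
  map: abc -> abc
- id: ldh_r
  equation: lac -> pyr
  map: abc -> abc
- id: lac_in
  equation: lac.ext -> lac
  map: abc -> abc
- id: lac_out
  equation: lac -> lac.out
  map: abc -> abc
- id: ala_syn
  equation: pyr -> ala
  map: abc -> abc
- id: ala_out
  equation: ala -> ala.out
  map: abc -> abc
- id: pyr_in
  equation: pyr.ext -> pyr
  map: abc -> abc
- id: pyr_out
  equation: pyr -> pyr.out
  map: abc -> abc
- id: pdh
  equation: pyr -> co2 + accoa
  map: abc -> a + bc
- id: pc
  equation: pyr + co2 -> oaa
  map: abc + d -> abcd
- id: cs
  equation: oaa + accoa -> cit
  map: abcd + ef -> dcbfea
- id: idh
  equation: cit -> akg + co2
  map: abcdef -> abcde + f
- id: akgdh
  equation: akg -> suc + co2
  map: abcde -> bcde + a
- id: sdh
  equation: suc -> fum
  map: abcd -> abcd
- id: fum_h
  equation: fum -> mal
  map: abcd -> abcd
- id: mdh
  equation: mal -> oaa
  map: abcd -> abcd
- id: asp_syn
  equation: oaa -> asp
  map: abcd -> abcd
- id: asp_out
  equation: asp -> asp.out
  map: abcd -> abcd
- id: glu_syn
  equation: akg -> glu
  map: abcde -> abcde
- id: glu_out
  equation: glu -> glu.out
  map: abcde -> abcde
- id: pro_syn
  equation: glu -> pro
  map: abcde -> abcde
- id: pro_out
  equation: pro -> pro.out
  map: abcde -> abcde
- id: cit_out
  equation: cit -> cit.out
  map: abcdef -> abcdef
- id: oaa_out
  equation: oaa -> oaa.out
  map: abcd -> abcd
- id: me1c
  equation: pyr + co2 -> mal
  map: abc + d -> abcd
- id: me1d
  equation: mal -> pyr + co2
  map: abcd -> abc + d
- id: ana
  equation: oaa.in -> oaa
  map: abcd -> abcd
symmetric:
- suc
- fum
co2: co2
co2_enrichment: 0.0
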