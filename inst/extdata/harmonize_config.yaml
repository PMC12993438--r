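# Harmonization configuration for the messy-sample fixture.
# Units map depth labels to a factor-to-metres; synonyms map lower-cased
# free-text environment terms to canonical enum values. Both tables are
# fixture constants of this package.
units:
  m: 1.0
  meter: 1.0
  meters: 1.0
  cm: 0.01
  mm: 0.001
  ft: 0.3048
  in: 0.0254
synonyms:
  dirt: soil
  topsoil: soil
  seawater: water
  sea water: water
  marine water: water
  freshwater: water
  atmosphere: air
  beach sand: sand
  dune sand: sand
  mud: sediment
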