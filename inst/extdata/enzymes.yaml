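# Restriction enzyme definitions (REBASE convention).
# cut_top / cut_bottom are signed offsets relative to the 3' boundary of the
# recognition site on the top strand:
#   BtsI  GCAGTG(2/0)  -> 2-nt 3' overhang
#   BsrDI GCAATG(2/0)  -> 2-nt 3' overhang
#   EcoRI G^AATTC      -> 4-nt 5' overhang
#   SpeI  A^CTAGT      -> 4-nt 5' overhang
BtsI:
  recognition: GCAGTG
  cut_top: 2
  cut_bottom: 0
BsrDI:
  recognition: GCAATG
  cut_top: 2
  cut_bottom: 0
EcoRI:
  recognition: GAATTC
  cut_top: -5
  cut_bottom: -1
SpeI:
  recognition: ACTAGT
  cut_top: -5
  cut_bottom: -1
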