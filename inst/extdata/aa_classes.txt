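# Default physicochemical partition of the 20 amino acids, used to pick
# class-preserving (isometric C2) control substitutions. One class per line:
# class_name = residues.
hydrophobic=AVILM
aromatic=FWY
polar_uncharged=STNQ
positive=KRH
negative=DE
special=GPC
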