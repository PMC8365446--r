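pattern_id,pattern,label,note
PNSP,^[PF]NSP$,NDP,diphosphate motif; phenylalanine tolerated at position 1
PAGR,^P[ASG]GR$,NTP,triphosphate motif; position 2 varies among A/S/G
PSMR,^PSMR$,NTP,methionine variant of the triphosphate motif; always with Ser at position 2
PQGSP,^P[QA]GSP$,NTP,five-residue triphosphate variant; Ala substitutes Gln at position 2
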