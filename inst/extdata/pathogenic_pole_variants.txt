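# POLE exonuclease-domain hotspot protein changes treated as pathogenic.
# One change per line; '#' starts a comment. Extend with additional
# recognized pathogenic changes as evidence accrues.
P286R
S297F
V411L
A456P
S459F
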