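>repeat_unit_1 Cnidoin repetitive sequence unit
QMQGCGQQMPPMMSGCGG
>repeat_unit_2 Cnidoin repetitive sequence unit
QMQGCGQQLPLMMPGCVG
>crd_antigen cysteine-rich domain antigen peptide
GCAPSCQQQCIPSCPRGCCGA
>ybbr_tag surface-anchoring tag
DSLEFIASKLA
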