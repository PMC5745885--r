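# Default tissue weight scheme, by severity of damage to the tissue:
#   1.0  damage immediately life threatening
#   0.8  damage life threatening
#   0.5  damage not immediately life threatening
#   0.3  damage not life threatening
#   0.0  tissue not affected / not a healthy-tissue sample
# Eye carries 0.5 because T cells are able to infiltrate it.
# Tissues not listed fall back to default_weight.
lung/respiratory system: 1.0
brain/nervous system: 1.0
blood/immune system: 1.0
heart: 1.0
liver: 1.0
digestive system: 0.8
soft tissue: 0.8
skin: 0.8
urinary bladder: 0.5
various glands: 0.5
prostate: 0.5
kidney: 0.5
eye: 0.5
reproductive organs: 0.3
mammary tissue: 0.3
tonsils: 0.3
cancer cell lines: 0.0
testis: 0.0
fetal tissue: 0.0
appendix: 0.0
gall bladder: 0.0
spleen: 0.0
default_weight: 0.5
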