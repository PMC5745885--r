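# Raw tissue labels (as found in protein-abundance and expression atlases,
# matched case-insensitively after trimming) -> canonical tissue names used
# by the default weight scheme. Users may supply their own map.
lung: lung/respiratory system
bronchus: lung/respiratory system
trachea: lung/respiratory system
nasopharynx: lung/respiratory system
brain: brain/nervous system
cerebral cortex: brain/nervous system
cerebellum: brain/nervous system
hippocampus: brain/nervous system
hypothalamus: brain/nervous system
spinal cord: brain/nervous system
caudate: brain/nervous system
blood: blood/immune system
whole blood: blood/immune system
bone marrow: blood/immune system
lymph node: blood/immune system
leukocyte: blood/immune system
heart: heart
heart muscle: heart
heart left ventricle: heart
atrial appendage: heart
liver: liver
colon: digestive system
stomach: digestive system
small intestine: digestive system
duodenum: digestive system
rectum: digestive system
esophagus: digestive system
oral mucosa: digestive system
salivary gland: various glands
pancreas: various glands
thyroid: various glands
thyroid gland: various glands
adrenal gland: various glands
parathyroid gland: various glands
pituitary: various glands
pituitary gland: various glands
adipose tissue: soft tissue
skeletal muscle: soft tissue
smooth muscle: soft tissue
muscle: soft tissue
skin: skin
skin of body: skin
urinary bladder: urinary bladder
bladder: urinary bladder
prostate: prostate
prostate gland: prostate
kidney: kidney
kidney cortex: kidney
eye: eye
retina: eye
ovary: reproductive organs
uterus: reproductive organs
cervix: reproductive organs
endometrium: reproductive organs
fallopian tube: reproductive organs
vagina: reproductive organs
seminal vesicle: reproductive organs
breast: mammary tissue
mammary gland: mammary tissue
tonsil: tonsils
tonsils: tonsils
testis: testis
testes: testis
placenta: fetal tissue
fetal brain: fetal tissue
fetal liver: fetal tissue
appendix: appendix
vermiform appendix: appendix
gall bladder: gall bladder
gallbladder: gall bladder
spleen: spleen
cell line: cancer cell lines
cancer cell line: cancer cell lines
hela: cancer cell lines
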