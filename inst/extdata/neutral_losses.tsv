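# Diagnostic neutral losses for the MSn rule engine.
# exact_mass / nominal_mass columns are derived from `formula` at load time;
# context tags which rule layer consumes the entry.
name	formula	context
water	H2O	generic
CO2	CO2	generic
dehydrated-hexose	C6H10O5	glycoside
dehydrated-deoxyhexose	C6H10O4	glycoside
dehydrated-pentose	C5H8O4	glycoside
dehydrated-glucuronate	C6H8O6	glycoside
threonate-H2O	C4H6O4	threonate-ester
putrescine	C4H12N2	amide
agmatine	C5H14N4	amide
spermidine	C7H19N3	amide
coumaroyl-H2O	C9H6O2	acyl
caffeoyl-H2O	C9H6O3	acyl
feruloyl-H2O	C10H8O3	acyl
sinapoyl-H2O	C11H10O4	acyl
malonyl-H2O	C3H2O3	acyl
RDA-catechin	C8H8O3	proanthocyanidin
RDA-gallocatechin	C8H8O4	proanthocyanidin
HRF	C6H6O3	proanthocyanidin
gallate-related	C7H4O4	proanthocyanidin
hydroxybenzoate-related	C7H4O2	proanthocyanidin
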