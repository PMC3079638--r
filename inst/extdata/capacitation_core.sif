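ATP	pp	PKA
ATP	pp	acrosomal ATPase
ATP	pp	actin polymerization
ATP	pp	membrane ATPase
ATP	pp	mitochondrial ATP synthesis
F-actin	pp	G-actin
F-actin	pp	actin polymerization
G-actin	pp	actin polymerization
OAM fusion	pp	actin polymerization
PKA	pp	PLD1
PKA	pp	[Ca2+]i
PLD1	pp	phosphatidic acid
PM fusion	pp	actin polymerization
[Ca2+]i	pp	acrosomal Ca store
[Ca2+]i	pp	actin polymerization
[Ca2+]i	pp	membrane Ca channel
[Ca2+]i	pp	mitochondrial Ca store
actin polymerization	pp	mitochondrial protein translation
actin polymerization	pp	phosphatidic acid
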