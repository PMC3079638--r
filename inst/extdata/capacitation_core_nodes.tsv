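#compartments: membrane, cytosol, cytoskeleton, mitochondria, acrosome, nucleus, extracellular
node	compartment
ATP	cytosol
F-actin	cytoskeleton
G-actin	cytoskeleton
OAM fusion	acrosome
PKA	cytosol
PLD1	membrane
PM fusion	membrane
[Ca2+]i	cytosol
acrosomal ATPase	acrosome
acrosomal Ca store	acrosome
actin polymerization	cytoskeleton
membrane ATPase	membrane
membrane Ca channel	membrane
mitochondrial ATP synthesis	mitochondria
mitochondrial Ca store	mitochondria
mitochondrial protein translation	mitochondria
phosphatidic acid	membrane
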