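surface	canonical
cholecalciferol	vitamin d
colecalciferol	vitamin d
ergocalciferol	vitamin d
vitamin d3	vitamin d
vitamin d2	vitamin d
colecalciferolum	vitamin d
ascorbic acid	ascorbic acid
vitamin c	ascorbic acid
acetylsalicylic acid	acetylsalicylic acid
aspirin	acetylsalicylic acid
asa	acetylsalicylic acid
paracetamol	paracetamol
acetaminophen	paracetamol
salbutamol	salbutamol
albuterol	salbutamol
levothyroxine	levothyroxine
l-thyroxine	levothyroxine
thyroxine	levothyroxine
esomeprazole	esomeprazole
nexium	esomeprazole
pantoprazole	pantoprazole
omeprazole	omeprazole
lansoprazole	lansoprazole
dexlansoprazole	dexlansoprazole
rabeprazole	rabeprazole
hydrochlorothiazide	hydrochlorothiazide
hctz	hydrochlorothiazide
furosemide	furosemide
frusemide	furosemide
chlorphenamine	chlorphenamine
chlorpheniramine	chlorphenamine
colecalciferol concentrate	vitamin d
folic acid	folic acid
vitamin b9	folic acid
cyanocobalamin	vitamin b12
vitamin b12	vitamin b12
glucosamine	glucosamine
magnesium	magnesium
metamizole	metamizole
dipyrone	metamizole
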