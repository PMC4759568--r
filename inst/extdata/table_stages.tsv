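drug	Stage I	Stage II	Stage III	Stage IV
1-benzhydryl-4-[(5-methyl-4-nitroisoxazol-3-yl)carbonyl]piperazine	X			
2-Chlor-N-(1-phenyl-3-propyl-1H-pyrazol-5-yl)acetamid	X			
4-{2-[(6-Chloro-4-quinazolinyl)amino]ethyl}phenol	X			
Ampicillin	X			X
clofarabine	X		X	
EMF-sumo1-12	X		X	X
etoposide	X			X
gemcitabine	X		X	X
HBEG	X			
idarubicin	X	X	X	X
INCA-6	X		X	
vanoxerine	X			
kinetin-riboside	X			
L755507	X			
N-[2-(allyloxy)benzyl]-N-1,3-benzodioxol-5-yl-2-chloroacetamide	X			
SA-792541	X			
SCH 79797 dihydrochloride	X			
Selamectin	X	X		X
Sepantronium	X			
teniposide	X			
3-(3-Benzoyl-6-chloro-4,5-dihydroxy-1-benzofuran-7-yl)-2,4-pentanedione		X		
AG-592		X		
Artesunate		X		
CD-437		X		
chrysenequinone		X		
cladribine		X		
cyclosporin-a		X		
IKK-2-inhibitor-V		X		
ingenol		X		
menadione		X		
N-[(5-Fluoro-8-hydroxy-7-quinolinyl)(2-thienyl)methyl]acetamide		X		
niclosamide		X		X
palbociclib		X		
Pevonedistat		X		
pyrvinium-pamoate		X	X	X
RO-28-1675		X		
triciribine		X		
wortmannin		X		
4-(4-Methoxyphenoxy)-2-(4-methylphenyl)-5-(2-thienyl)-3(2H)-pyridazinone			X	
6-(1,3-Benzodioxol-5-yl)-N-(cyclopentylmethyl)-4-quinazolinamine			X	
BIBR-1532			X	
ixazomib			X	
methyl-2,5-dihydroxycinnamate			X	X
mifepristone			X	
milrinone			X	
N’-[(E)-(2,3-Dihydroxyphenyl)methylene]-2-hydroxybenzohydrazide			X	
N-[5-(4-Morpholinylsulfonyl)-2-(1-pyrrolidinyl)phenyl]-4,5,6,7-tetrahydro-1-benzothiophene-2-carboxamide			X	
paroxetine			X	
ruxolitinib			X	
SA-1478088			X	
SCH-79797			X	
SKF-83959			X	
2-Dichloromethyl-4-ethylsulfanyl-6-phenyl-[1,3,5]triazine				X
4-{[5-(1-Naphthyl)-1,3,4-oxadiazol-2-yl]sulfanyl}-2-butyn-1-yl				X
BAS-02859604				X
calmidazolium				X
homoharringtonine				X
irinotecan				X
KM-03949SC				X
quizartinib				X
rhodomyrtoxin-b				X
TPCA-1				X
trichostatin-a				X
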