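drug	LuminalA	LuminalB	HER2	TripleNegative
4-[4-(4-Fluorobenzyl)-1-piperidinyl]thieno[2,3-d]pyrimidine	X			
5-[(Benzyloxy)methyl]-7-(1-piperidinylmethyl)-8-quinolinol	X	X		
6-(2,3-Dihydro-1,4-benzodioxin-6-yl)-N-(3-methylbenzyl)-4-quinazolinamine	X			
CD-437	X		X	X
chlorambucil	X	X		
cladribine	X			X
etoposide	X	X	X	X
gemcitabine	X		X	
heliomycin	X			
ingenol	X	X		
L-690488	X	X		
lonidamine	X			
methylene-blue	X	X		
N-[(5-Bromo-8-hydroxy-7-quinolinyl)(2-thienyl)methyl]acetamide	X			
N-[(5-Fluoro-8-hydroxy-7-quinolinyl)(2-thienyl)methyl]acetamide	X	X		
PAC-1	X			
palbociclib	X		X	
tunicamycin	X			
vorinostat	X		X	
wortmannin	X	X	X	X
4-(keto-methyl-oxido-sulfuraniumyl)-3-nitro-benzoic		X		
benzamide		X		
benzydamine		X		
diphenyleneiodonium		X		
menadione		X		
NM-PP1		X		
NVP-BEZ235		X		
obatoclax		X		
quinoclamine		X		
RO-28-1675		X		
serdemetan		X		
ZM-241385		X		
aminopurvalanol-a			X	
barasertib			X	
cytarabine			X	X
dasatinib			X	
entinostat			X	
fluticasone			X	
KIN001-055			X	
purvalanol-a			X	
pyrvinium-pamoate			X	X
SIB-1893			X	X
trichostatin-a			X	
triciribine			X	
tubastatin-a			X	X
WZ-4002			X	
(4E)-2-(4-Methoxyphenyl)-4-[(4-methoxyphenyl)imino]-4H-chromen-6-ol				X
5-[(Benzyloxy)methyl]-7-(1-pyrrolidinylmethyl)-8-quinolinol				X
chrysenequinone				X
clobetasol				X
cyclosporin-a				X
idarubicin				X
K784-3187				X
PLX-4720				X
teniposide				X
WAY-170523				X
withaferin-a				X
WYE-125132				X
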