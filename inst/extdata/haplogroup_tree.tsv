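name	parent	cr_motif	coding_diagnostics
ROOT			
R0	ROOT		
HV0	R0	16298C	
H	R0		7028:C
H1	H		3010:A
H1bh	H1		11377:T
H2a	H		4769:T
H3	H		6776:G
H4	H		3992:T
H5'36	H		456:A
H6a	H		3915:T
H7	H		4793:C
H8	H		13101:C
H9	H		13020:C
H10	H		14470:A
H11	H		8448:G
H12	H		3936:T
H13a1	H		4745:G
H15	H		6253:C
JT	ROOT	73G,16126C	
J	JT	16069T,295T	
J1	J	228A	
J1c	J1	185A	
J1c1	J1c	16261T	
J1c2	J1c	188G	
J2	J	150T,152C	
T	JT	16294T	
U	ROOT	73G	11467:G
U5	U	16270T	
U5a	U5	16256C	
U5a1b1	U5a	16399G	
U5b	U5	150T	
U5b1c1a	U5b	16189C	
U6a	U	16172C,16219G,16278T	
K	U	16224C,16311C	
K1a	K	497T	
K2a	K	16352C	
K2a5	K2a	16148T	
W	ROOT	16223T,16292T,204C	
X2	ROOT	16223T,16278T,153G	
L1b	ROOT	16187T,16223T,16264T	
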