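gene	allele	position	residue
DRB1	15:01	-5	Met
DRB1	16:01	-5	Met
DRB1	03:01	-5	Thr
DRB1	13:03	-5	Thr
DRB1	04:01	-5	Thr
DRB1	04:04	-5	Thr
DRB1	14:01	-5	Thr
DRB1	01:01	-5	Thr
DRB1	07:01	-5	Thr
DRB1	11:01	-5	Thr
DRB1	13:01	-5	Thr
DRB1	08:01	-5	Thr
DRB1	12:01	-5	Thr
DRB1	09:01	-5	Thr
DRB1	15:01	11	Pro
DRB1	16:01	11	Pro
DRB1	03:01	11	Ser
DRB1	13:03	11	Ser
DRB1	04:01	11	Val
DRB1	04:04	11	Val
DRB1	14:01	11	Ser
DRB1	01:01	11	Leu
DRB1	07:01	11	Gly
DRB1	11:01	11	Ser
DRB1	13:01	11	Ser
DRB1	08:01	11	Ser
DRB1	12:01	11	Ser
DRB1	09:01	11	Asp
DRB1	15:01	13	Arg
DRB1	16:01	13	Arg
DRB1	03:01	13	Ser
DRB1	13:03	13	Ser
DRB1	04:01	13	His
DRB1	04:04	13	His
DRB1	14:01	13	Ser
DRB1	01:01	13	Phe
DRB1	07:01	13	Tyr
DRB1	11:01	13	Ser
DRB1	13:01	13	Ser
DRB1	08:01	13	Gly
DRB1	12:01	13	Gly
DRB1	09:01	13	Phe
DRB1	15:01	57	Asp
DRB1	16:01	57	Asp
DRB1	03:01	57	Asp
DRB1	13:03	57	Asp
DRB1	04:01	57	Asp
DRB1	04:04	57	Asp
DRB1	14:01	57	Asp
DRB1	01:01	57	Asp
DRB1	07:01	57	Val
DRB1	11:01	57	Asp
DRB1	13:01	57	Asp
DRB1	08:01	57	Asp
DRB1	12:01	57	Ala
DRB1	09:01	57	Ser
DRB1	15:01	71	Ala
DRB1	16:01	71	Ala
DRB1	03:01	71	Lys
DRB1	13:03	71	Lys
DRB1	04:01	71	Lys
DRB1	04:04	71	Arg
DRB1	14:01	71	Arg
DRB1	01:01	71	Arg
DRB1	07:01	71	Arg
DRB1	11:01	71	Arg
DRB1	13:01	71	Glu
DRB1	08:01	71	Arg
DRB1	12:01	71	Arg
DRB1	09:01	71	Arg
DRB1	15:01	74	Ala
DRB1	16:01	74	Ala
DRB1	03:01	74	Arg
DRB1	13:03	74	Ala
DRB1	04:01	74	Ala
DRB1	04:04	74	Ala
DRB1	14:01	74	Glu
DRB1	01:01	74	Ala
DRB1	07:01	74	Gln
DRB1	11:01	74	Ala
DRB1	13:01	74	Ala
DRB1	08:01	74	Leu
DRB1	12:01	74	Ala
DRB1	09:01	74	Glu
DRB1	15:01	86	Val
DRB1	16:01	86	Gly
DRB1	03:01	86	Val
DRB1	13:03	86	Val
DRB1	04:01	86	Gly
DRB1	04:04	86	Val
DRB1	14:01	86	Val
DRB1	01:01	86	Gly
DRB1	07:01	86	Gly
DRB1	11:01	86	Gly
DRB1	13:01	86	Val
DRB1	08:01	86	Gly
DRB1	12:01	86	Gly
DRB1	09:01	86	Gly
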