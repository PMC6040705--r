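sample	gene	allele1	allele2
trio_case1	DRB1	07:01:01	12:01:01
trio_father	DRB1	10:01:01	12:01:01
trio_mother	DRB1	07:01:01	08:01:01
case2	DRB1	13:01:01	15:01:01
case3	DRB1	13:01:01	15:01:01
case4	DRB1	13:01:01	15:01:01
case5	DRB1	11:01:02	15:01:01
case6	DRB1	04:03:01	15:03:01
case7	DRB1	03:01:01	13:01:01
case8	DRB1	15:01:01	14:01:01
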