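sample	role	father	mother	hla_drb1_1	hla_drb1_2	ftcd_gt
trio_case1	case	trio_father	trio_mother	07:01:01	12:01:01	2/2
trio_father	parent	NA	NA	10:01:01	12:01:01	1/1
trio_mother	parent	NA	NA	07:01:01	08:01:01	1/2
case2	case	NA	NA	13:01:01	13:01:01	1/2
case3	case	NA	NA	13:01:01	15:01:01	1/1
case4	case	NA	NA	13:01:01	15:01:01	1/1
case5	case	NA	NA	11:01:02	15:01:01	1/1
case6	case	NA	NA	04:05:01	15:03:01	1/1
case7	case	NA	NA	03:01:01	13:01:01	1/1
case8	case	NA	NA	15:01:01	14:54:01	1/1
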