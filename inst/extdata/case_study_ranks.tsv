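disease	method	position	rank
gastric cancer	FVTLDA_MLR	1	1
gastric cancer	FVTLDA_MLR	2	2
gastric cancer	FVTLDA_MLR	3	4
gastric cancer	FVTLDA_MLR	4	5
gastric cancer	FVTLDA_MLR	5	6
gastric cancer	FVTLDA_MLR	6	7
gastric cancer	FVTLDA_MLR	7	9
gastric cancer	FVTLDA_MLR	8	10
gastric cancer	FVTLDA_MLR	9	29
gastric cancer	FVTLDA_MLR	10	11
gastric cancer	FVTLDA_ANN	1	1
gastric cancer	FVTLDA_ANN	2	3
gastric cancer	FVTLDA_ANN	3	2
gastric cancer	FVTLDA_ANN	4	4
gastric cancer	FVTLDA_ANN	5	7
gastric cancer	FVTLDA_ANN	6	5
gastric cancer	FVTLDA_ANN	7	13
gastric cancer	FVTLDA_ANN	8	10
gastric cancer	FVTLDA_ANN	9	8
gastric cancer	FVTLDA_ANN	10	42
gastric cancer	KATZLDA	1	1
gastric cancer	KATZLDA	2	2
gastric cancer	KATZLDA	3	3
gastric cancer	KATZLDA	4	4
gastric cancer	KATZLDA	5	5
gastric cancer	KATZLDA	6	6
gastric cancer	KATZLDA	7	27
gastric cancer	KATZLDA	8	7
gastric cancer	KATZLDA	9	34
gastric cancer	KATZLDA	10	10
leukemia	FVTLDA_MLR	1	1
leukemia	FVTLDA_MLR	2	2
leukemia	FVTLDA_MLR	3	3
leukemia	FVTLDA_MLR	4	4
leukemia	FVTLDA_MLR	5	5
leukemia	FVTLDA_MLR	6	6
leukemia	FVTLDA_MLR	7	9
leukemia	FVTLDA_MLR	8	10
leukemia	FVTLDA_ANN	1	1
leukemia	FVTLDA_ANN	2	4
leukemia	FVTLDA_ANN	3	2
leukemia	FVTLDA_ANN	4	3
leukemia	FVTLDA_ANN	5	5
leukemia	FVTLDA_ANN	6	10
leukemia	FVTLDA_ANN	7	6
leukemia	FVTLDA_ANN	8	7
leukemia	KATZLDA	1	1
leukemia	KATZLDA	2	3
leukemia	KATZLDA	3	2
leukemia	KATZLDA	4	4
leukemia	KATZLDA	5	5
leukemia	KATZLDA	6	8
leukemia	KATZLDA	7	6
leukemia	KATZLDA	8	9
lung cancer	FVTLDA_MLR	1	1
lung cancer	FVTLDA_MLR	2	2
lung cancer	FVTLDA_MLR	3	3
lung cancer	FVTLDA_MLR	4	4
lung cancer	FVTLDA_MLR	5	6
lung cancer	FVTLDA_MLR	6	7
lung cancer	FVTLDA_MLR	7	8
lung cancer	FVTLDA_MLR	8	20
lung cancer	FVTLDA_ANN	1	1
lung cancer	FVTLDA_ANN	2	2
lung cancer	FVTLDA_ANN	3	5
lung cancer	FVTLDA_ANN	4	6
lung cancer	FVTLDA_ANN	5	11
lung cancer	FVTLDA_ANN	6	10
lung cancer	FVTLDA_ANN	7	4
lung cancer	FVTLDA_ANN	8	9
lung cancer	KATZLDA	1	4
lung cancer	KATZLDA	2	45
lung cancer	KATZLDA	3	51
lung cancer	KATZLDA	4	49
lung cancer	KATZLDA	5	63
lung cancer	KATZLDA	6	20
lung cancer	KATZLDA	7	60
lung cancer	KATZLDA	8	54
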