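condition	n_channels	epoch_s	subject	accuracy_pct	itr_bit_per_min
1ch_3s	1	3	S1	60.00	11.02
1ch_3s	1	3	S2	60.00	11.02
1ch_3s	1	3	S3	86.67	29.78
1ch_3s	1	3	S4	73.33	19.04
1ch_3s	1	3	S5	76.67	21.43
3ch_3s	3	3	S1	60.00	11.02
3ch_3s	3	3	S2	73.33	19.04
3ch_3s	3	3	S3	76.67	21.43
3ch_3s	3	3	S4	70.00	16.81
3ch_3s	3	3	S5	73.33	19.04
1ch_4s	1	4	S1	66.67	11.06
1ch_4s	1	4	S2	63.33	9.61
1ch_4s	1	4	S3	93.33	27.53
1ch_4s	1	4	S4	83.33	20.08
1ch_4s	1	4	S5	80.00	18.00
3ch_4s	3	4	S1	83.33	20.08
3ch_4s	3	4	S2	73.33	14.28
3ch_4s	3	4	S3	93.33	27.53
3ch_4s	3	4	S4	83.33	20.08
3ch_4s	3	4	S5	83.33	20.08
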