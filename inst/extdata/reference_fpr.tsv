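modality	subject	fpr_per_min
eb	S1	0.19
eb	S2	0
eb	S3	0
eb	S4	0.19
eb	S5	0.19
emg	S1	0.19
emg	S2	0
emg	S3	0
emg	S4	0.1
emg	S5	0.1
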