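##gff-version 3
# Synthetic rDNA transcription-unit annotation (coordinate frame only).
# 7800 nt total; the 5'ETS occupies the first 1300 nt. Internal boundaries
# are plausible fission-yeast-like sizes chosen for examples/tests and do
# not reproduce any reference annotation.
rDNA	cracpause	transcription_unit	1	7800	.	+	.	ID=rdna_unit;Name=rdna_unit
rDNA	cracpause	region	1	1300	.	+	.	ID=r1;Parent=rdna_unit;Name=5ETS
rDNA	cracpause	region	1301	3100	.	+	.	ID=r2;Parent=rdna_unit;Name=18S
rDNA	cracpause	region	3101	3460	.	+	.	ID=r3;Parent=rdna_unit;Name=ITS1
rDNA	cracpause	region	3461	3620	.	+	.	ID=r4;Parent=rdna_unit;Name=5.8S
rDNA	cracpause	region	3621	4520	.	+	.	ID=r5;Parent=rdna_unit;Name=ITS2
rDNA	cracpause	region	4521	7620	.	+	.	ID=r6;Parent=rdna_unit;Name=25S
rDNA	cracpause	region	7621	7800	.	+	.	ID=r7;Parent=rdna_unit;Name=3ETS
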