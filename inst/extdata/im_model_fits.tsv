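# Isolation-with-migration model fits for the albatross two-population
# analysis: maximized log-likelihood and estimated-parameter count per
# nested model. fixed_params lists the parameters constrained in each model.
label	logL	k	fixed_params
Pop. size BF = LA; Mig. from LA to BF = 0	2.48	3	q1;M0>1
Mig. from LA to BF = 0	3.39	4	M0>1
Anc. pop. size = BF; Mig. from LA to BF = 0	2.16	3	q2;M0>1
Anc pop. size = LA; Mig. from LA to BF = 0	2.16	3	q2;M0>1
Mig. from BF to LA = mig. from LA to BF	2.99	4	M1>0
Pop. size LA = BF	2.48	4	q1
Mig. from LA to BF = 0; Pop. size LA & BF = anc	0.30	2	q1;q2;M0>1
Anc pop. Size = BF	2.16	4	q2
LA pop. size = anc	2.16	4	q2
BF pop. size = LA; Mig. from LA to BF = BF to LA	0.93	3	q1;M1>0
Full model	2.60	5	none
BF pop. size = LA & anc	0.30	3	q1;q2
BF pop. size = LA; Both mig. = 0	-0.83	2	q1;M0>1;M1>0
Both mig. = 0	-0.19	3	M0>1;M1>0
BF pop. size = LA & anc; Mig. From LA to BF = BF to LA	-1.21	2	q1;q2;M1>0
LA pop. size = anc; Mig. from LA to BF = BF to LA	-0.69	3	q2;M1>0
BF pop. size = anc; Both mig. = 0	-1.78	2	q2;M0>1;M1>0
BF pop. size = LA; Mig. from BF to LA = 0	-0.83	3	q1;M1>0
BF pop. size = anc; Mig. from LA to BF = BF to LA	-0.85	3	q2;M1>0
LA pop. size = anc; Mig. from BF to LA = 0	-0.86	3	q2;M1>0
BF pop. size = LA & anc; Mig. from BF to LA = 0	-2.06	2	q1;q2;M1>0
Mig. from BF to LA = 0	-0.19	4	M1>0
BF pop. size = anc; Mig. from BF to LA = 0	-1.60	3	q2;M1>0
LA pop. size = anc; Both mig. = 0	-3.53	2	q2;M0>1;M1>0
BF pop. size = LA & anc.; Both mig. = 0	-4.97	1	q1;q2;M0>1;M1>0
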