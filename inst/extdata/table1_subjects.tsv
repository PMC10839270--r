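subject_id	sex	age	sleep
A	Ma	30	6.5
B	Fe	31	8.25
C	Fe	29	7.75
D	Ma	38	8
E	Fe	29	8
F	Fe	31	7.75
G	Ma	24	7.25
H	Fe	28	7
I	Ma	27	8.25
J	Ma	41	7
K	Ma	30	8.75
L	Fe	29	8
M	Ma	31	8.25
N	Ma	28	NA
O	Ma	43	7.25
P	Fe	28	7.75
Q	Ma	30	7.5
R	Fe	31	6
S	Fe	36	6.5
T	Fe	30	7.25
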