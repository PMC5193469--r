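case_id	chromosome	nucleus_id	n_red	n_green
case-01	chr1	1	1	2
case-01	chr1	2	1	2
case-01	chr1	3	1	2
case-01	chr1	4	1	2
case-01	chr1	5	1	2
case-01	chr1	6	0	2
case-01	chr1	7	1	2
case-01	chr1	8	1	2
case-01	chr1	9	1	2
case-01	chr1	10	0	2
case-01	chr1	11	2	2
case-01	chr1	12	1	2
case-01	chr1	13	1	2
case-01	chr1	14	2	2
case-01	chr1	15	1	2
case-01	chr1	16	1	2
case-01	chr1	17	1	2
case-01	chr1	18	0	2
case-01	chr1	19	1	3
case-01	chr1	20	1	2
case-01	chr1	21	1	1
case-01	chr1	22	2	2
case-01	chr1	23	2	2
case-01	chr1	24	1	1
case-01	chr1	25	2	2
case-01	chr1	26	1	1
case-01	chr1	27	1	2
case-01	chr1	28	1	1
case-01	chr1	29	1	2
case-01	chr1	30	1	2
case-01	chr9	1	1	1
case-01	chr9	2	0	1
case-01	chr9	3	1	1
case-01	chr9	4	1	1
case-01	chr9	5	0	1
case-01	chr9	6	1	1
case-01	chr9	7	3	2
case-01	chr9	8	1	1
case-01	chr9	9	2	2
case-01	chr9	10	1	1
case-01	chr9	11	2	1
case-01	chr9	12	1	1
case-01	chr9	13	1	0
case-01	chr9	14	1	0
case-01	chr9	15	1	1
case-01	chr9	16	2	2
case-01	chr9	17	1	1
case-01	chr9	18	1	1
case-01	chr9	19	2	2
case-01	chr9	20	1	1
case-01	chr9	21	3	2
case-01	chr9	22	1	1
case-01	chr9	23	1	1
case-01	chr9	24	1	1
case-01	chr9	25	1	1
case-01	chr9	26	1	1
case-01	chr9	27	1	1
case-01	chr9	28	1	1
case-01	chr9	29	0	1
case-01	chr9	30	0	1
case-02	chr1	1	2	1
case-02	chr1	2	1	1
case-02	chr1	3	2	1
case-02	chr1	4	2	1
case-02	chr1	5	2	2
case-02	chr1	6	1	2
case-02	chr1	7	2	2
case-02	chr1	8	1	2
case-02	chr1	9	2	2
case-02	chr1	10	2	1
case-02	chr1	11	1	2
case-02	chr1	12	2	2
case-02	chr1	13	2	2
case-02	chr1	14	1	2
case-02	chr1	15	2	2
case-02	chr1	16	2	2
case-02	chr1	17	2	2
case-02	chr1	18	2	2
case-02	chr1	19	2	2
case-02	chr1	20	2	2
case-02	chr1	21	2	2
case-02	chr1	22	1	1
case-02	chr1	23	2	2
case-02	chr1	24	2	2
case-02	chr1	25	1	2
case-02	chr1	26	2	2
case-02	chr1	27	1	1
case-02	chr1	28	2	1
case-02	chr1	29	2	2
case-02	chr1	30	2	2
case-02	chr9	1	3	3
case-02	chr9	2	2	2
case-02	chr9	3	2	3
case-02	chr9	4	2	2
case-02	chr9	5	3	3
case-02	chr9	6	3	3
case-02	chr9	7	3	3
case-02	chr9	8	2	3
case-02	chr9	9	2	2
case-02	chr9	10	3	3
case-02	chr9	11	3	2
case-02	chr9	12	3	3
case-02	chr9	13	3	3
case-02	chr9	14	3	2
case-02	chr9	15	2	1
case-02	chr9	16	3	3
case-02	chr9	17	3	4
case-02	chr9	18	3	3
case-02	chr9	19	2	2
case-02	chr9	20	3	2
case-02	chr9	21	3	2
case-02	chr9	22	2	2
case-02	chr9	23	3	3
case-02	chr9	24	3	1
case-02	chr9	25	2	3
case-02	chr9	26	3	3
case-02	chr9	27	3	2
case-02	chr9	28	3	3
case-02	chr9	29	3	3
case-02	chr9	30	3	3
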