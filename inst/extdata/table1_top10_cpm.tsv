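population	rank	gene_id	mirna	cpm	percent
Mk	1	406966	miR-191-5p	231441	23.1
Mk	2	723876	miR-486-5p	195803	19.6
Mk	3	407056	miR-99b-5p	164315	16.4
Mk	4	574447	miR-146b-5p	65671	6.6
Mk	5	407015/407016	miR-26a-5p	39625	4.0
Mk	6	406888/406889	let-7f-5p	23623	2.4
Mk	7	406913	miR-126-5p	22642	2.3
Mk	8	406938	miR-146a-5p	21993	2.2
Mk	9	406991	miR-21-5p	20197	2.0
Mk	10	406940	miR-148a-3p	17054	1.7
MkMP	1	723876	miR-486-5p	164087	16.4
MkMP	2	406966	miR-191-5p	117782	11.8
MkMP	3	407015/407016	miR-26a-5p	91774	9.2
MkMP	4	406888/406889	let-7f-5p	68251	6.8
MkMP	5	407048/407049	miR-92a-3p	44480	4.4
MkMP	6	406913	miR-126-5p	44218	4.4
MkMP	7	407004	miR-22-3p	43152	4.3
MkMP	8	406991	miR-21-5p	38617	3.9
MkMP	9	574447	miR-146b-5p	34455	3.4
MkMP	10	406995/406996	miR-181a-5p	33752	3.4
PLT	1	406966	miR-191-5p	263871	26.4
PLT	2	723876	miR-486-5p	80546	8.1
PLT	3	406888/406889	let-7f-5p	76283	7.6
PLT	4	407056	miR-99b-5p	71050	7.1
PLT	5	406902	miR-10a-5p	54139	5.4
PLT	6	407015/407016	miR-26a-5p	51712	5.2
PLT	7	406938	miR-146a-5p	43647	4.4
PLT	8	407048/407049	miR-92a-3p	43032	4.3
PLT	9	574447	miR-146b-5p	25104	2.5
PLT	10	406995/406996	miR-181a-5p	23932	2.4
PLP	1	406966	miR-191-5p	162495	16.2
PLP	2	723876	miR-486-5p	146874	14.7
PLP	3	407015/407016	miR-26a-5p	84857	8.5
PLP	4	406888/406889	let-7f-5p	64288	6.4
PLP	5	574447	miR-146b-5p	49986	5.0
PLP	6	406913	miR-126-5p	43506	4.4
PLP	7	407056	miR-99b-5p	42826	4.3
PLP	8	406991	miR-21-5p	40419	4.0
PLP	9	407004	miR-22-3p	32727	3.3
PLP	10	406995/406996	miR-181a-5p	25520	2.6
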