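sample_id	group	rs1816753	rs12476635	rs74599577	rs77820970
C001	control	C/T	T/T	A/A	C/C
C002	control	C/C	T/T	A/A	C/C
C003	control	C/C	T/T	A/A	C/C
C004	control	C/C	C/T	A/A	C/C
C005	control	C/C	T/T	A/A	C/C
C006	control	C/C	C/T	A/A	C/C
C007	control	C/T	C/T	A/A	C/C
C008	control	T/T	T/T	A/A	C/C
C009	control	T/T	T/T	A/A	C/C
C010	control	C/C	T/T	A/A	C/C
C011	control	C/T	T/T	A/A	C/C
C012	control	C/C	T/T	A/A	C/C
C013	control	T/T	T/T	A/A	C/C
C014	control	C/T	T/T	A/A	C/C
C015	control	T/T	T/T	A/A	C/C
C016	control	C/C	T/T	A/A	C/C
C017	control	C/T	T/T	A/A	C/C
C018	control	C/T	C/T	A/A	C/C
C019	control	C/C	T/T	A/A	C/C
C020	control	C/T	T/T	A/A	C/C
C021	control	C/T	C/T	A/A	C/C
C022	control	C/T	T/T	A/A	C/C
C023	control	C/T	T/T	A/A	C/C
C024	control	C/T	T/T	A/A	C/C
C025	control	C/C	T/T	A/A	C/C
C026	control	C/C	T/T	A/A	C/C
C027	control	C/C	T/T	A/A	C/C
C028	control	C/C	T/T	A/A	C/C
P001	patient	C/C	T/T	A/A	C/C
P002	patient	C/C	T/T	A/A	C/C
P003	patient	C/T	T/T	A/A	C/C
P004	patient	C/C	T/T	A/A	C/C
P005	patient	C/T	T/T	A/A	T/T
P006	patient	C/C	T/T	A/A	C/C
P007	patient	C/C	T/T	A/A	C/C
P008	patient	C/T	T/T	A/A	C/C
P009	patient	C/T	T/T	A/T	C/T
P010	patient	C/C	T/T	A/A	C/C
P011	patient	C/C	T/T	A/A	C/C
P012	patient	C/C	T/T	A/A	C/T
P013	patient	C/C	T/T	A/A	C/T
P014	patient	C/C	C/T	A/A	C/C
P015	patient	C/C	T/T	A/A	C/C
P016	patient	C/C	C/T	A/A	C/C
P017	patient	C/C	T/T	A/A	C/C
P018	patient	C/T	T/T	A/A	C/C
P019	patient	C/T	T/T	A/A	C/C
P020	patient	C/T	T/T	A/A	C/T
P021	patient	C/C	C/T	A/A	C/C
P022	patient	C/T	T/T	A/A	C/C
P023	patient	C/T	T/T	A/A	T/T
P024	patient	T/T	C/T	A/A	C/T
P025	patient	C/T	T/T	A/A	C/C
P026	patient	C/C	T/T	A/A	C/T
P027	patient	C/C	T/T	A/T	C/T
P028	patient	C/C	T/T	A/A	C/C
P029	patient	C/C	T/T	A/A	T/T
P030	patient	C/T	T/T	A/A	C/C
P031	patient	C/C	T/T	A/A	C/T
P032	patient	C/C	T/T	A/A	C/C
P033	patient	C/C	T/T	A/A	C/T
P034	patient	C/C	T/T	A/A	C/C
P035	patient	C/C	T/T	A/A	C/C
P036	patient	C/C	T/T	A/A	C/T
P037	patient	C/T	T/T	A/A	C/C
P038	patient	C/C	C/C	A/A	C/C
P039	patient	C/T	T/T	A/A	C/T
P040	patient	C/T	C/T	A/A	C/C
P041	patient	C/C	T/T	A/A	C/C
P042	patient	C/C	T/T	A/A	C/C
P043	patient	C/C	C/T	A/A	C/C
P044	patient	C/T	T/T	A/A	C/C
P045	patient	C/T	T/T	A/A	C/C
P046	patient	C/C	T/T	A/A	C/C
P047	patient	C/C	T/T	A/A	C/C
P048	patient	C/C	T/T	A/T	C/T
P049	patient	C/T	T/T	A/A	C/C
P050	patient	C/T	T/T	A/A	C/T
P051	patient	C/C	T/T	A/A	C/C
P052	patient	C/C	T/T	A/A	C/T
P053	patient	C/T	C/T	A/A	C/T
P054	patient	C/T	T/T	A/A	C/C
P055	patient	C/C	T/T	A/T	C/T
P056	patient	C/C	T/T	A/A	C/T
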