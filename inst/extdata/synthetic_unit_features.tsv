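name	start	end	note
processing_site_01	1	10	synthetic position, 5'ETS primary cleavage
processing_site_A0	1500	1509	synthetic position, 5'ETS
processing_site_1	3657	3666	synthetic position, 5'ETS/18S boundary
C_box	6000	6020	synthetic position, ITS1 cis-acting element
processing_site_2	6590	6599	synthetic position, ITS1/5.8S boundary
SalT1_box	20000	20030	synthetic position, IGS replication fork barrier
SalT2_box	20500	20530	synthetic position, IGS replication fork barrier
SalT3_box	21000	21030	synthetic position, IGS replication fork barrier
SalT4_box	21500	21530	synthetic position, IGS replication fork barrier
SalT5_box	22000	22030	synthetic position, IGS replication fork barrier
CTCF_site	42000	42018	synthetic position, IGS
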