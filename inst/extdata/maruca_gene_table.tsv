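# Maruca vitrata mitochondrial gene feature table (GenBank HZ751150, partial genome).
# Coordinates are printed in transcription orientation (start5 > stop3 for most
# L-strand rows); declared_length is carried verbatim even where it disagrees
# with coordinate arithmetic (several L-strand rows are short by 2).
name	ftype	strand	start5	stop3	declared_length	start_codon	stop_codon
nd2	PCG	H	1	999	999	TTA	TAA
trnW	tRNA	H	1007	1074	68
trnC	tRNA	H	1068	1131	64
trnY	tRNA	L	1199	1137	61
cox1	PCG	H	1207	2739	1533	CGA	TAA
trnL-UUR	tRNA	H	2735	2801	67
cox2	PCG	H	2802	3486	685	ATG	T
trnK	tRNA	H	3484	3554	71
trnD	tRNA	L	3557	3624	68
atp8	PCG	H	3624	3785	162	ATT	TAA
atp6	PCG	H	3779	4453	675	ATG	TAA
cox3	PCG	H	4461	5249	789	ATG	TAA
trnG	tRNA	H	5252	5317	66
nd3	PCG	H	5318	5671	354	ATT	TAA
trnA	tRNA	H	5673	5738	66
trnR	tRNA	H	5737	5802	66
trnN	tRNA	H	5801	5866	66
trnS-AGN	tRNA	H	5869	5936	68
trnE	tRNA	H	5937	6001	65
trnF	tRNA	L	6069	6004	64
nd5	PCG	L	7790	6260	1529	ATT	TAA
trnH	tRNA	L	7872	7806	65
nd4	PCG	L	9213	7872	1340	ATG	TAA
nd4L	PCG	L	9491	9213	277	ATG	TAA
trnT	tRNA	H	9465	9532	68
trnP	tRNA	L	9591	9531	59
nd6	PCG	H	9611	10040	430	ATT	TAA
cytb	PCG	H	10377	11364	988
trnS-UCN	tRNA	H	11367	11432	66
nd1	PCG	L	12378	11449	928	TTG	TAG
trnL-CUN	tRNA	L	12455	12388	66
rrnL	rRNA	L	13780	12476	1303
trnV	tRNA	L	13852	13804	47
rrnS	rRNA	L	13863	14139	277
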