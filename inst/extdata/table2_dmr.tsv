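# Differential DNA methylation regions reported for F3-generation granulosa cells
# (digitized reference table; 43 records). Coordinates are on the rat rn4 build
# used by the array annotation; region_size = end - start for every row.
gene_symbol	gene_description	entrez_id	significance	chr	start	end	region_size
Ceacam9	Carcinoembryonic antigen-related cell adhesion molecule 9	116711	8.53E-46	1	76960699	76961299	600
Sv2b	Synaptic vesicle glycoprotein 2b	117556	1.93E-61	1	130887128	130887728	600
Dtx4	Deltex homolog 4 (Drosophila)	293774	4.98E-14	1	215416136	215416736	600
Vdac1	Voltage-dependent anion channel 1	83529	2.12E-11	10	37793541	37794141	600
Rpl26	Ribosomal protein L26	287417	1.75E-28	10	55660989	55661674	685
Olr1468	olfactory receptor 1468	404977	1.23E-13	10	60268062	60268662	600
Cuedc1	CUE domain containing 1	303419	1.28E-08	10	76394145	76394745	600
Plekhm1	pleckstrin homology domain containing, family M (with RUN domain) member 1	303584	1.17E-34	10	92604304	92604904	600
RGD1563888	similar to DNA segment, Chr 16, ERATO Doi 472, expressed	360692	1.71E-31	11	17477532	17478132	600
Olr1567	olfactory receptor 1567	287970	2.23E-29	11	83619053	83619653	600
Selplg	selectin P ligand	363930	8.29E-10	12	43842412	43843012	600
Prom1	prominin 1	60357	3.57E-08	14	72118855	72119731	876
Lif	leukemia inhibitory factor	60584	5.55E-08	14	84886415	84887207	792
C1d	C1D nuclear receptor co-repressor	289810	1.46E-08	14	98152531	98153207	676
Zrsr1	zinc finger (CCCH type), RNA binding motif and serine/arginine rich 1	498425	1.69E-10	14	103657219	103657819	600
Gnpnat1	glucosamine-phosphate N-acetyltransferase 1	498486	8.05E-104	15	21287426	21288462	1036
Hars	histidyl-tRNA synthetase	307492	2.25E-08	15	60151437	60152140	703
LOC689713	LRRGT00175	689713	5.22E-30	16	83676467	83677258	791
Edn1	endothelin 1	24323	1.12E-11	17	28311735	28312730	995
Pcdha5	protocadherin alpha 5	393087	1.40E-39	18	29691331	29692216	885
Dtwd2	DTW domain containing 2	361326	3.36E-18	18	44718539	44719362	823
Mcm5	minichromosome maintenance complex component 5	291885	6.05E-15	19	13975188	13975788	600
Adcy7	adenylate cyclase 7	84420	4.10E-08	19	20076391	20076991	600
Dhps	deoxyhypusine synthase	288923	7.38E-10	19	24744799	24745688	889
Sv2a	synaptic vesicle glycoprotein 2a	117559	8.57E-27	2	190988570	190989259	689
Olr1686	olfactory receptor gene	294152	2.06E-09	20	417292	417892	600
Agpat1	1-acylglycerol-3-phosphate O-acyltransferase 1 (lysophosphatidic acid acyltransferase, alpha)	406165	1.91E-15	20	4243966	4244790	824
LOC686922	glutathione S-transferase, theta 4	686922	1.22E-09	20	13236150	13237231	1081
Unc5b	unc-5 homolog B (C. elegans)	60630	2.06E-21	20	28165595	28166390	795
Lcn11	lipocalin 11	100169711	3.73E-15	3	3888286	3888886	600
Lamc3	laminin gamma 3	311862	1.11E-21	3	10985872	10986472	600
Olr425	olfactory receptor 425	296687	1.05E-09	3	16610744	16611459	715
Serf2	small EDRK-rich factor 2	502663	4.86E-14	3	108254804	108255580	776
Vom1r102	vomeronasal 1 receptor 102	286957	9.69E-08	4	124241988	124242588	600
Ppap2b	phosphatidic acid phosphatase type 2B	192270	4.56E-31	5	126121326	126122026	700
Ctrc	chymotrypsin C (caldecrin)	362653	2.41E-27	5	160755960	160756730	770
Clip4	CAP-GLY domain containing linker protein family, member 4	298801	3.02E-17	6	23831232	23832132	900
Olr1016	olfactory receptor 1016	288858	6.29E-25	7	6876471	6877071	600
Rabl2b	RAB, member of RAS oncogene family-like 2B	362987	1.17E-28	7	127910262	127910992	730
Nfkbie	nuclear factor of kappa light polypeptide gene enhancer in B-cells inhibitor, epsilon	316241	5.02E-12	9	11053187	11053787	600
Aox3	aldehyde oxidase 3	493909	1.65E-14	9	56779670	56780578	908
Rpl39	ribosomal protein L39	25347	9.66E-17	X	7824369	7825465	1096
Nxf7	nuclear RNA export factor 7	501621	8.46E-20	X	122897736	122898626	890
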