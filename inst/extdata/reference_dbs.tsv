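metabolite_id	name	formula	neutral_mass	pathway_map	pathway_name	origin_class	ppi_forming
HMDB0000645	Galactose-1-phosphate	C6H13O9P	260.029719	map00052	Galactose Metabolism	endogenous	yes
HMDB0000730	Isobutyrylglycine	C6H11NO3	145.073893	map00280	Valine, Leucine and Isoleucine Degradation	endogenous	no
HMDB0000510	Aminoadipic acid	C6H11NO4	161.068808	map00310	Lysine Metabolism	endogenous	no
HMDB0013639	8-[(Aminomethyl)sulfanyl]-6-sulfanyloctanoic acid	C9H19NO2S2	237.085721	map00071	Fatty Acid Synthesis/Beta-Oxidation	endogenous	no
HMDB0012236	Imidazole acetol-phosphate	C6H9N2O5P	220.024908	map00340	Histidine Metabolism	endogenous	no
HMDB0006029	N-Acetylglutamine	C7H12N2O4	188.079707	map00250	Glutamate Metabolism	endogenous	yes
HMDB0011173	Glycyl-Hydroxyproline	C7H12N2O4	188.079707	map00250	Glutamate Metabolism	endogenous	no
HMDB0000107	Galactitol	C6H14O6	182.079038	map00052	Galactose Metabolism	endogenous	yes
HMDB0000206	N6-Acetyl-L-lysine	C8H16N2O3	188.116092	map00310	Lysine Metabolism	endogenous	no
HMDB0012281	Portulacaxanthin II	C18H18N2O7	374.111401	map00965	Betalain Metabolism	endogenous	no
HMDB0012148	2-Hexaprenyl-6-methoxy-1,4-benzoquinol	C37H56O3	548.422946	map00130	Ubiquinone and other Terpenoid-quinone Biosynthesis	endogenous	yes
HMDB0002421	7-Sulfocholic acid	C24H40O8S	488.244389	map00120,map00121	Bile Acid Synthesis	endogenous	no
HMDB0003361	Pyrimidine	C4H4N2	80.037448	map00240	Pyrimidine Metabolism	endogenous	yes
HMDB0006488	N-Acetyl-L-glutamate 5-semialdehyde	C7H11NO4	173.068808	map00330	Arginine and Proline Metabolism	endogenous	yes
HMDB0011714	Vanilpyruvic acid	C10H10O5	210.052823		Nutrition	endogenous	no
HMDB0028967	Methionyl-Arginine	C11H23N5O3S	305.152161		Incomplete Protein Degradation	endogenous	no
HMDB0029028	Prolyl-Tryptophan	C16H19N3O3	301.142641		Incomplete Protein Degradation	endogenous	no
HMDB0059788	Hemorphin-4	C29H35N5O7	565.253648		Blood Regulation	endogenous	no
HMDB0006409	Tyramine-O-sulfate	C8H11NO4S	217.040879		Nutrition	endogenous	no
HMDB0000479	3-Methylhistidine	C7H11N3O2	169.085127		Muscle Degradation	endogenous	no
DECOY00001	Synthetic decoy 1		557.905182			endogenous	no
DECOY00002	Synthetic decoy 2		252.922940			endogenous	no
DECOY00003	Synthetic decoy 3		545.918713	map90003	Synthetic pathway 3	endogenous	no
DECOY00004	Synthetic decoy 4		388.827756			endogenous	no
DECOY00005	Synthetic decoy 5		187.136088			exogenous	no
DECOY00006	Synthetic decoy 6		452.590760			exogenous	no
DECOY00007	Synthetic decoy 7		390.157526			endogenous	unknown
DECOY00008	Synthetic decoy 8		437.530354			endogenous	no
DECOY00009	Synthetic decoy 9		234.292090	map90009	Synthetic pathway 9	endogenous	yes
DECOY00010	Synthetic decoy 10		160.833011			endogenous	no
DECOY00011	Synthetic decoy 11		244.208891			endogenous	no
DECOY00012	Synthetic decoy 12		342.407605			drug	no
DECOY00013	Synthetic decoy 13		507.395580			endogenous	no
DECOY00014	Synthetic decoy 14		193.573842			endogenous	unknown
DECOY00015	Synthetic decoy 15		413.572604			drug	no
DECOY00016	Synthetic decoy 16		497.690150			endogenous	no
DECOY00017	Synthetic decoy 17		391.454224			endogenous	no
DECOY00018	Synthetic decoy 18		266.654100	map90018	Synthetic pathway 18	endogenous	no
DECOY00019	Synthetic decoy 19		112.284613			exogenous	no
DECOY00020	Synthetic decoy 20		174.426190			drug	no
DECOY00021	Synthetic decoy 21		164.435013	map90021	Synthetic pathway 21	endogenous	unknown
DECOY00022	Synthetic decoy 22		456.614387			exogenous	no
DECOY00023	Synthetic decoy 23		406.340129			endogenous	no
DECOY00024	Synthetic decoy 24		328.898080			exogenous	no
DECOY00025	Synthetic decoy 25		522.838899			endogenous	no
DECOY00026	Synthetic decoy 26		377.684269			endogenous	no
DECOY00027	Synthetic decoy 27		224.710834	map90027	Synthetic pathway 27	endogenous	no
DECOY00028	Synthetic decoy 28		269.250603			endogenous	unknown
DECOY00029	Synthetic decoy 29		401.191622			drug	no
DECOY00030	Synthetic decoy 30		124.159514			exogenous	no
DECOY00031	Synthetic decoy 31		310.545278			exogenous	no
DECOY00032	Synthetic decoy 32		335.277451			endogenous	no
DECOY00033	Synthetic decoy 33		462.176690	map90033	Synthetic pathway 33	endogenous	no
DECOY00034	Synthetic decoy 34		210.424568			endogenous	no
DECOY00035	Synthetic decoy 35		435.324276			endogenous	unknown
DECOY00036	Synthetic decoy 36		173.338197			exogenous	no
DECOY00037	Synthetic decoy 37		192.693827			endogenous	no
DECOY00038	Synthetic decoy 38		461.280114			drug	no
DECOY00039	Synthetic decoy 39		534.565141	map90039	Synthetic pathway 39	endogenous	no
DECOY00040	Synthetic decoy 40		276.460002			endogenous	no
DECOY00041	Synthetic decoy 41		540.448224			endogenous	no
DECOY00042	Synthetic decoy 42		477.262648			exogenous	unknown
DECOY00043	Synthetic decoy 43		255.856457			exogenous	no
DECOY00044	Synthetic decoy 44		195.714824			exogenous	no
DECOY00045	Synthetic decoy 45		228.807392			drug	no
DECOY00046	Synthetic decoy 46		372.582998			endogenous	no
DECOY00047	Synthetic decoy 47		367.817518			drug	no
DECOY00048	Synthetic decoy 48		161.346458			exogenous	no
DECOY00049	Synthetic decoy 49		464.559445			drug	unknown
DECOY00050	Synthetic decoy 50		406.761130			endogenous	no
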