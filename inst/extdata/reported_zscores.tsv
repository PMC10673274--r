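compound	z_I.1	z_II.1	z_II.3	affected_pathway	hmdb_id	kegg_id	ppi_formation	section
Galactose-1-phosphate	0.569	6.475	5.690	Galactose Metabolism	HMDB0000645	map00052	+	pathway-mapped
Isobutyrylglycine	1.355	2.823	6.566	Valine, Leucine and Isoleucine Degradation	HMDB0000730	map00280	-	pathway-mapped
Aminoadipic acid	0.626	2.458	4.823	Lysine Metabolism	HMDB0000510	map00310	-	pathway-mapped
8-[(Aminomethyl)sulfanyl]-6-sulfanyloctanoic acid	1.561	3.116	3.964	Fatty Acid Synthesis/Beta-Oxidation	HMDB0013639	map00071	-	pathway-mapped
Imidazole acetol-phosphate	-0.328	2.325	4.607	Histidine Metabolism	HMDB0012236	map00340	-	pathway-mapped
N-Acetylglutamine | Glycyl-Hydroxyproline	0.700	3.434	2.965	Glutamate Metabolism	HMDB0006029 | HMDB0011173	map00250	+	pathway-mapped
Galactitol	-0.624	3.156	2.812	Galactose Metabolism	HMDB0000107	map00052	+	pathway-mapped
N6-Acetyl-L-lysine	0.822	2.990	2.691	Lysine Metabolism	HMDB0000206	map00310	-	pathway-mapped
Portulacaxanthin II	-0.102	2.811	2.947	Betalain Metabolism	HMDB0012281	map00965	-	pathway-mapped
2-Hexaprenyl-6-methoxy-1,4-benzoquinol	-0.845	3.064	2.234	Ubiquinone and other Terpenoid-quinone Biosynthesis	HMDB0012148	map00130	+	pathway-mapped
7-Sulfocholic acid	-1.741	2.289	2.982	Bile Acid Synthesis	HMDB0002421	map00120, map00121	-	pathway-mapped
Pyrimidine	0.887	2.069	2.489	Pyrimidine Metabolism	HMDB0003361	map00240	+	pathway-mapped
N-Acetyl-L-glutamate 5-semialdehyde	0.247	2.002	2.114	Arginine and Proline Metabolism	HMDB0006488	map00330	+	pathway-mapped
Vanilpyruvic acid	-2.226	4.723	2.692	Nutrition	HMDB0011714	NA	-	unmapped
Methionyl-Arginine	-0.911	2.863	3.539	Incomplete Protein Degradation	HMDB0028967	NA	-	unmapped
Prolyl-Tryptophan	1.498	3.010	2.379	Incomplete Protein Degradation	HMDB0029028	NA	-	unmapped
Hemorphin-4	-0.352	2.233	2.422	Blood Regulation	HMDB0059788	NA	-	unmapped
Tyramine-O-sulfate	-0.811	2.285	2.159	Nutrition	HMDB0006409	NA	-	unmapped
3-Methylhistidine	1.449	2.183	2.221	Muscle Degradation	HMDB0000479	NA	-	unmapped
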