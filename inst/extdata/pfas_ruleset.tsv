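order	subclass	class	pattern
1	PFCAs	PFAAs	CnF2n+1-COOH; single carboxyl, remainder fully fluorinated
2	PFSAs	PFAAs	CnF2n+1-SO3H; single sulfonic head, remainder fully fluorinated
3	PFPAs	PFAAs	CnF2n+1-P(=O)(OH)2; phosphonic head, one chain
4	PFPiAs	PFAAs	(CnF2n+1)2-P(=O)OH; phosphinic head, two chains
5	PFECAs	PFAAs	perfluoroether carboxylic acid: C/F/O only, one COOH, >=1 ether O, all other carbons fully fluorinated (housed under PFAAs)
6	PFESAs	PFAAs	perfluoroether sulfonic acid: C/F/O/S only, one SO3H, >=1 ether O, all carbons fully fluorinated (housed under PFAAs)
7	FASAAs	FASA_based_PFAA_precursors	CnF2n+1-SO2N(CmH2m+1)-CH2COOH sulfonamidoacetic acid
8	FASACs	FASA_based_PFAA_precursors	CnF2n+1-SO2N(CmH2m+1)-C2H4-O-C(=O)CH=CH2 sulfonamidoethyl acrylate
9	FASMACs	FASA_based_PFAA_precursors	CnF2n+1-SO2N(CmH2m+1)-C2H4-O-C(=O)C(CH3)=CH2 sulfonamidoethyl methacrylate
10	FASEs	FASA_based_PFAA_precursors	CnF2n+1-SO2N(CmH2m+1)-C2H4OH sulfonamidoethanol
11	FASAs	FASA_based_PFAA_precursors	CnF2n+1-SO2N(H/CmH2m+1)2 sulfonamide
12	FTUCAs	fluorotelomer_based_PFAA_precursors	CnF2n+1-CF=CH-COOH unsaturated carboxylic acid
13	FTUALs	fluorotelomer_based_PFAA_precursors	CnF2n+1-CF=CH-CHO unsaturated aldehyde
14	FTCAs	fluorotelomer_based_PFAA_precursors	CnF2n+1-CH2-COOH carboxylic acid
15	FTALs	fluorotelomer_based_PFAA_precursors	CnF2n+1-CH2-CHO aldehyde
16	FTACs	fluorotelomer_based_PFAA_precursors	CnF2n+1-C2H4-O-C(=O)CH=CH2 acrylate (n:2)
17	FTMACs	fluorotelomer_based_PFAA_precursors	CnF2n+1-C2H4-O-C(=O)C(CH3)=CH2 methacrylate (n:2)
18	FTSAs	fluorotelomer_based_PFAA_precursors	CnF2n+1-C2H4-SO3H sulfonic acid (n:2)
19	diPAPs	fluorotelomer_based_PFAA_precursors	(CnF2n+1-C2H4-O)2-P(=O)OH phosphate diester
20	monoPAPs	fluorotelomer_based_PFAA_precursors	CnF2n+1-C2H4-O-P(=O)(OH)2 phosphate monoester
21	FTIs	fluorotelomer_based_PFAA_precursors	CnF2n+1-C2H4-I iodide (n:2)
22	FTOs	fluorotelomer_based_PFAA_precursors	CnF2n+1-CH=CH2 olefin
23	FTOHs	fluorotelomer_based_PFAA_precursors	CnF2n+1-C2H4-OH alcohol (n:2)
24	PASFs	perfluoroalkyl_PFAA_precursors	CnF2n+1-SO2F/Cl sulfonyl halide
25	PAFs	perfluoroalkyl_PFAA_precursors	CnF2n+1-C(=O)F acyl fluoride
26	PFAIs	perfluoroalkyl_PFAA_precursors	CnF2n+1-I iodide on chain
27	perfluoroketones	non_PFAA_perfluoroalkyls	C/F/O only, all oxygens ketonic, all carbons fully fluorinated
28	perfluoroalcohols	non_PFAA_perfluoroalkyls	C/F/O only, all oxygens hydroxyl, all carbons fully fluorinated
29	perfluoroalkenes	non_PFAA_perfluoroalkyls	C/F only with a C=C double bond, no hydrogens
30	perfluoroalkanes	non_PFAA_perfluoroalkyls	C/F only, saturated, no hydrogens (CnF2n+2)
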