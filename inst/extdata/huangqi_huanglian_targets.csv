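target_id,name,uniprot_id,gene
T-01,Estrogen receptor,P03372,ESR1
T-02,Estrogen receptor beta,Q92731,ESR2
T-03,Peroxisome proliferator-activated receptor alpha,Q07869,PPARA
T-04,Peroxisome proliferator activated receptor gamma,P37231,PPARG
T-05,Superoxide dismutase [Cu-Zn],P00441,SOD1
T-06,Hepatocyte nuclear factor 4-alpha,P41235,HNF4A
T-07,Prostaglandin G/H synthase 2,P35354,PTGS2
T-08,Calmodulin-1,P0DP23,CALM1
T-09,5-Hydroxytryptamine 2C receptor,P28335,HTR2C
T-10,Vascular endothelial growth factor A,P15692,VEGFA
T-11,"Nitric oxide synthase, inducible",P35228,NOS2
T-12,"Nitric oxide synthase, endothelial",P29474,NOS3
T-13,Glucocorticoid receptor,P04150,NR3C1
T-14,Interleukin-1 beta,P01584,IL1B
T-15,Heme oxygenase 1,P09601,HMOX1
T-16,"Phosphatidylinositol-4,5-bisphosphate 3-kinase catalytic subunit, gamma isoform",P48736,PIK3CG
T-17,Tumor necrosis factor,P01375,TNF
T-18,Glutathione S-transferase Mu 1,P09488,GSTM1
T-19,Acetylcholinesterase,P22303,AChE
T-20,Caspase-3,P42574,CASP3
T-21,Caspase-9,P55211,CASP9
T-22,"mRNA of protein-tyrosine phosphatase, non-receptor type 1",P18031,PTP1B
T-23,Glucagon-like peptide 1 receptor,P43220,GLP1R
T-24,Aldose reductase,P15121,AKR1B1
T-25,"Solute carrier family 2, facilitated glucose transporter member 2",P11166,GLUT2
T-26,"Solute carrier family 2, facilitated glucose transporter member 4",P14672,GLUT4
T-27,Interleukin-2,P60568,IL2
T-28,Interleukin-6,P05231,IL6
T-29,Hepatocyte nuclear factor 1-alpha,P20823,HNF1A
T-30,Glucokinase,P35557,GCK
T-31,Insulin-degrading enzyme,P14735,IDE
T-32,Insulin-like growth factor 1 receptor,P08069,IGF1R
T-33,Insulin receptor,P06213,INSR
T-34,Lysosomal alpha-glucosidase,P10253,GAA
T-35,Phosphatidylinositol 3-kinase regulatory subunit alpha,P27986,PIK3R1
T-36,Dipeptidyl peptidase IV,P27487,DPP4
T-37,C-C motif chemokine 2,P13500,CCL2
T-38,Glycogen synthase kinase-3 beta,P49841,GSK3B
T-39,Glutathione S-transferase Mu 2,P28161,GSTM2
T-40,Mitogen-activated protein kinase 1,P28482,MAPK1
T-41,Mitogen-activated protein kinase 14,Q16539,MAPK14
T-42,Beta-2 adrenergic receptor,P07550,ADRB2
T-43,NAD(P)H dehydrogenase [quinone] 1,P15559,NQO1
T-44,78 kDa glucose-regulated protein,P11021,HSPA5
T-45,Glycogen phosphorylase,P06737,PYGL
T-46,Farnesoid X receptor,B6ZGS9,FXR
T-47,5'-AMP-activated protein kinase catalytic subunit alpha-2,P54646,AMPK
T-48,Pancreatic alpha-amylase,P04746,AMY2A
T-49,Cytochrome P450 3A4,P08684,CYP3A4
T-50,Cyclin-dependent kinase 2,P24941,CDK2
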