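id,name,chem_class,smiles,fa,operator
cypermethrin,Cypermethrin,pyrethroid,CC1(C)C(C=C(Cl)Cl)C1C(=O)OC(C#N)c1cccc(Oc2ccccc2)c1,0.40,=
deltamethrin,Deltamethrin,pyrethroid,CC1(C)C(C=C(Br)Br)C1C(=O)OC(C#N)c1cccc(Oc2ccccc2)c1,0.48,>
permethrin,Permethrin,pyrethroid,CC1(C)C(C=C(Cl)Cl)C1C(=O)OCc1cccc(Oc2ccccc2)c1,0.32,>=
bendiocarb,Bendiocarb,carbamate,CNC(=O)Oc1cccc2c1OC(C)(C)O2,0.99,>=
pirimicarb,Pirimicarb,carbamate,CN(C)C(=O)Oc1nc(nc(C)c1C)N(C)C,0.74,=
molinate,Molinate,carbamate,CCSC(=O)N1CCCCCC1,0.40,>
propoxur,Propoxur,carbamate,CNC(=O)Oc1ccccc1OC(C)C,0.37,>
ddt,DDT,organochlorine,Clc1ccc(cc1)C(c1ccc(Cl)cc1)C(Cl)(Cl)Cl,0.15,=
pentachlorophenol,Pentachlorophenol,organochlorine,Oc1c(Cl)c(Cl)c(Cl)c(Cl)c1Cl,0.86,>
tcdd,TCDD,organochlorine,Clc1cc2Oc3cc(Cl)c(Cl)cc3Oc2cc1Cl,0.87,>
chlorpyrifos,Chlorpyrifos,organophosphorus,CCOP(=S)(OCC)Oc1nc(Cl)c(Cl)cc1Cl,0.82,=
diazinon,Diazinon,organophosphorus,CCOP(=S)(OCC)Oc1cc(C)nc(n1)C(C)C,0.66,>
dichlorvos,Dichlorvos,organophosphorus,COP(=O)(OC)OC=C(Cl)Cl,0.36,>
dimethoate,Dimethoate,organophosphorus,CNC(=O)CSP(=S)(OC)OC,0.86,=
fenitrothion,Fenitrothion,organophosphorus,COP(=S)(OC)Oc1ccc(c(C)c1)[N+](=O)[O-],0.81,=
parathion,Parathion,organophosphorus,CCOP(=S)(OCC)Oc1ccc(cc1)[N+](=O)[O-],0.46,>
propetamphos,Propetamphos,organophosphorus,CC(=CC(=O)OC(C)C)OP(=S)(OC)NCC,0.41,>
t_2_4_5,"2,4,5-T",miscellaneous,OC(=O)COc1cc(Cl)c(Cl)cc1Cl,0.89,>
d_2_4,"2,4-D",miscellaneous,OC(=O)COc1ccc(Cl)cc1Cl,0.85,=
fluazifop_butyl,Fluazifop-butyl,miscellaneous,CCCCOC(=O)C(C)Oc1ccc(Oc2ccc(cn2)C(F)(F)F)cc1,0.88,=
mcpa,MCPA,miscellaneous,Cc1cc(Cl)ccc1OCC(=O)O,0.55,>
paraquat,Paraquat,miscellaneous,C[n+]1ccc(cc1)-c1cc[n+](C)cc1,0.05,<=
picloram,Picloram,miscellaneous,Nc1c(Cl)c(nc(Cl)c1Cl)C(O)=O,0.91,=
triclopyr,Triclopyr,miscellaneous,OC(=O)COc1nc(Cl)c(Cl)cc1Cl,0.82,>
warfarine,Warfarine,miscellaneous,CC(=O)CC(c1ccccc1)C1=C(O)c2ccccc2OC1=O,0.93,>
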