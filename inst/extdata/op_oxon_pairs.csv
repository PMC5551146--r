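id,name,chem_class,smiles,role,parent_id
bensulide,Bensulide,organophosphorus,CC(C)OP(=S)(OC(C)C)SCCNS(=O)(=O)c1ccccc1,parent,
chlorpyrifos,Chlorpyrifos,organophosphorus,CCOP(=S)(OCC)Oc1nc(Cl)c(Cl)cc1Cl,parent,
chlorpyrifos_methyl,Chlorpyrifos-methyl,organophosphorus,COP(=S)(OC)Oc1nc(Cl)c(Cl)cc1Cl,parent,
coumaphos,Coumaphos,organophosphorus,CCOP(=S)(OCC)Oc1ccc2c(c1)OC(=O)C(Cl)=C2C,parent,
diazinon,Diazinon,organophosphorus,CCOP(=S)(OCC)Oc1cc(C)nc(n1)C(C)C,parent,
ethion,Ethion,organophosphorus,CCOP(=S)(OCC)SCSP(=S)(OCC)OCC,parent,
fenthion,Fenthion,organophosphorus,COP(=S)(OC)Oc1ccc(SC)c(C)c1,parent,
fonofos,Fonofos,organophosphorus,CCOP(=S)(CC)Sc1ccccc1,parent,
malathion,Malathion,organophosphorus,CCOC(=O)CC(SP(=S)(OC)OC)C(=O)OCC,parent,
methyl_parathion,Methyl-parathion,organophosphorus,COP(=S)(OC)Oc1ccc(cc1)[N+](=O)[O-],parent,
parathion,Parathion,organophosphorus,CCOP(=S)(OCC)Oc1ccc(cc1)[N+](=O)[O-],parent,
phorate,Phorate,organophosphorus,CCOP(=S)(OCC)SCSCC,parent,
phosmet,Phosmet,organophosphorus,COP(=S)(OC)SCN1C(=O)c2ccccc2C1=O,parent,
sulprofos,Sulprofos,organophosphorus,CCOP(=S)(SCCC)Oc1ccc(SC)cc1,parent,
terbufos,Terbufos,organophosphorus,CCOP(=S)(OCC)SCSC(C)(C)C,parent,
bensulide_oxon,Bensulide oxon,organophosphorus,CC(C)OP(=O)(OC(C)C)SCCNS(=O)(=O)c1ccccc1,oxon_metabolite,bensulide
chlorpyrifos_oxon,Chlorpyrifos-oxon,organophosphorus,CCOP(=O)(OCC)Oc1nc(Cl)c(Cl)cc1Cl,oxon_metabolite,chlorpyrifos
chlorpyrifos_methyl_oxon,Chlorpyrifos-methyl-oxon,organophosphorus,COP(=O)(OC)Oc1nc(Cl)c(Cl)cc1Cl,oxon_metabolite,chlorpyrifos_methyl
coumaphos_oxon,Coumaphos oxon (coroxon),organophosphorus,CCOP(=O)(OCC)Oc1ccc2c(c1)OC(=O)C(Cl)=C2C,oxon_metabolite,coumaphos
diazinon_oxon,Diazoxon,organophosphorus,CCOP(=O)(OCC)Oc1cc(C)nc(n1)C(C)C,oxon_metabolite,diazinon
ethion_oxon,Ethion monoxon,organophosphorus,CCOP(=O)(OCC)SCSP(=S)(OCC)OCC,oxon_metabolite,ethion
fenthion_oxon,Fenthion oxon (fenoxon),organophosphorus,COP(=O)(OC)Oc1ccc(SC)c(C)c1,oxon_metabolite,fenthion
fonofos_oxon,Fonofos oxon,organophosphorus,CCOP(=O)(CC)Sc1ccccc1,oxon_metabolite,fonofos
malathion_oxon,Malaoxon,organophosphorus,CCOC(=O)CC(SP(=O)(OC)OC)C(=O)OCC,oxon_metabolite,malathion
methyl_parathion_oxon,Methyl-paraoxon,organophosphorus,COP(=O)(OC)Oc1ccc(cc1)[N+](=O)[O-],oxon_metabolite,methyl_parathion
parathion_oxon,Paraoxon,organophosphorus,CCOP(=O)(OCC)Oc1ccc(cc1)[N+](=O)[O-],oxon_metabolite,parathion
phorate_oxon,Phorate oxon,organophosphorus,CCOP(=O)(OCC)SCSCC,oxon_metabolite,phorate
phosmet_oxon,Phosmet oxon,organophosphorus,COP(=O)(OC)SCN1C(=O)c2ccccc2C1=O,oxon_metabolite,phosmet
sulprofos_oxon,Sulprofos oxon,organophosphorus,CCOP(=O)(SCCC)Oc1ccc(SC)cc1,oxon_metabolite,sulprofos
terbufos_oxon,Terbufos oxon,organophosphorus,CCOP(=O)(OCC)SCSC(C)(C)C,oxon_metabolite,terbufos
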