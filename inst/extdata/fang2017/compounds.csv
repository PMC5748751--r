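id,name,subclass,R3,R5,R6,R7,R8,R2p,R3p,R4p,R5p,is_glycoside
1,Flavone,flavone,H,H,H,H,H,H,H,H,H,FALSE
2,Tangertin,flavone,H,OMe,OMe,OMe,OMe,H,H,OMe,H,FALSE
3,Wogonin,flavone,H,OH,H,OH,OMe,H,H,H,H,FALSE
4,Baicalein,flavone,H,OH,OH,OH,H,H,H,H,H,FALSE
5,Luteolin,flavone,H,OH,H,OH,H,H,OH,OH,H,FALSE
6,Apigenin,flavone,H,OH,H,OH,H,H,H,OH,H,FALSE
7,Chrysin,flavone,H,OH,H,OH,H,H,H,H,H,FALSE
8,Schaftoside,flavone,H,OH,Cglc,OH,Carb,H,H,OH,H,TRUE
9,Galangin,flavonol,OH,OH,H,OH,H,H,H,H,H,FALSE
10,Quercetin,flavonol,OH,OH,H,OH,H,H,OH,OH,H,FALSE
11,Morin,flavonol,OH,OH,H,OH,H,OH,H,OH,H,FALSE
12,Kaempferol,flavonol,OH,OH,H,OH,H,H,H,OH,H,FALSE
13,Kaempferide,flavonol,OH,OH,H,OH,H,H,H,OMe,H,FALSE
14,Myricetin,flavonol,OH,OH,H,OH,H,H,OH,OH,OH,FALSE
15,Isorhamnetin,flavonol,OH,OH,H,OH,H,H,OMe,OH,H,FALSE
16,Quercitrin,flavonol,Orha,OH,H,OH,H,H,OH,OH,H,TRUE
17,Rutin,flavonol,ORG,OH,H,OH,H,H,OH,OH,H,TRUE
18,Hesperetin,flavanone,H,OH,H,OH,H,H,OH,OMe,H,FALSE
19,Naringenin,flavanone,H,OH,H,OH,H,H,H,OH,H,FALSE
20,Naringin,flavanone,H,OH,H,ONG,H,H,H,OH,H,TRUE
21,Liquiritigenin,flavanone,H,H,H,OH,H,H,H,OH,H,FALSE
22,Taxifolin,flavanone,OH,OH,H,OH,H,H,OH,OH,H,FALSE
23,Formononetin,isoflavone,-,H,OH,H,H,H,OMe,H,H,FALSE
24,Puerarin,isoflavone,-,H,H,OH,Cglc,H,H,OH,H,TRUE
25,Glycitein,isoflavone,-,H,OMe,OH,H,H,H,OH,H,FALSE
26,Daidzein,isoflavone,-,H,H,OH,H,H,H,OH,H,FALSE
27,Genistein,isoflavone,-,OH,H,OH,H,H,H,OH,H,FALSE
28,Biochanin A,isoflavone,-,OH,H,OH,H,H,H,OMe,H,FALSE
29,Isoliquiritigenin,chalcone,OH,OH,-,-,-,H,H,OH,H,FALSE
30,Neohesperidin dihydrochalcone,dihydrochalcone,NG,OH,-,-,-,H,OH,OMe,H,TRUE
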