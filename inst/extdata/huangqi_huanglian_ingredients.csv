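ingredient_id,name,herb,mw,clogp,nhdon,nhacc,ob,dl,rescue
M1,Berberine,Huanglian,,,,,0.68,0.78,TRUE
M2,Columbamine,Huanglian,,,,,26.94,0.59,TRUE
M3,Berberrubine,Huanglian,,,,,35.74,0.73,FALSE
M4,8-Oxocoptisine,Huanglian,,,,,46.83,0.89,FALSE
M10,Magnoflorine,Huanglian,,,,,22.60,0.55,TRUE
M12,Epiberberine,Huanglian,,,,,43.09,0.78,FALSE
M13,Groenlandicine,Huanglian,,,,,28.42,0.72,TRUE
M16,Phellodendrine,Huanglian,,,,,2.50,0.58,TRUE
M18,(R)-Canadine,Huanglian,,,,,55.37,0.77,FALSE
M19,Berlambine,Huanglian,,,,,36.68,0.82,FALSE
M20,Jatrorrhizine,Huanglian,,,,,19.65,0.59,TRUE
M21,Palmatine,Huanglian,,,,,64.60,0.65,FALSE
M23,Coptisine,Huanglian,,,,,7.21,0.86,TRUE
M26,Worenine,Huanglian,,,,,45.83,0.87,FALSE
M27,Obacunone,Huanglian,,,,,43.29,0.77,FALSE
M32,Ferulic acid,Huanglian,,,,,39.56,0.06,TRUE
M33,Vanillic acid,Huanglian,,,,,35.47,0.04,TRUE
M60,beta-Sitosterol,Huanglian/Huangqi,,,,,36.23,0.78,FALSE
M61,Hederagenin,Huangqi,,,,,36.91,0.75,FALSE
M62,Lupeol,Huangqi,,,,,12.12,0.78,TRUE
M85,Soyasaponin I,Huangqi,,,,,2.06,0.15,TRUE
M92,Astragaloside I,Huangqi,,,,,46.79,0.11,TRUE
M94,Astragaloside II,Huangqi,,,,,0.79,0.13,TRUE
M96,Astragaloside III,Huangqi,,,,,31.83,0.10,TRUE
M98,Astragaloside IV,Huangqi,,,,,2.20,0.15,TRUE
M104,Isoastragaloside I,Huangqi,,,,,37.80,0.14,TRUE
M109,Cycloastragenol,Huangqi,,,,,25.70,0.10,TRUE
M115,Kumatakenin,Huangqi,,,,,50.83,0.29,FALSE
M118,Isorhamnetin,Huangqi,,,,,49.60,0.31,FALSE
M119,"3,9-di-O-Methylnissolin",Huangqi,,,,,53.74,0.48,FALSE
M120,Calycosin,Huangqi,,,,,47.75,0.24,FALSE
M121,Calycosin 7-O-beta-D-glucopyranoside,Huangqi,,,,,10.05,0.81,TRUE
M122,7-O-Methylisomucronulatol,Huangqi,,,,,74.69,0.30,FALSE
M123,"(6aR,11aR) 3-Hydroxy-9,10-dimethoxypterocarpan-3-O-beta-D-glucoside",Huangqi,,,,,36.74,0.92,FALSE
M124,"(6aR,11aR) 3-Hydroxy-9,10-dimethoxypterocarpan",Huangqi,,,,,64.26,0.42,FALSE
M125,Formononetin,Huangqi,,,,,69.67,0.21,FALSE
M126,Formononetin-7-O-beta-D-glucoside,Huangqi,,,,,11.52,0.78,TRUE
M127,Rhamnocitrin-3-O-glucoside,Huangqi,,,,,2.87,0.76,TRUE
M132,Isomucronulatol,Huangqi,,,,,67.67,0.26,FALSE
M141,Rutin,Huanglian/Huangqi,,,,,11.70,0.68,TRUE
M148,Quercetin,Huanglian/Huangqi,,,,,46.43,0.28,FALSE
M154,Kaempferol,Huanglian/Huangqi,,,,,67.43,0.24,FALSE
M171,Astragalus polysaccharides,Huangqi,,,,,,,TRUE
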