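country,abbrev,cluster,sample_size,n_hybrids
Bosnia and Herzegovina,WBos,Balkans,13,7
Bulgaria,WBul,Balkans,5,1
Croatia,WCro,Balkans,15,0
Greece,WGre,Balkans,8,1
Serbia,WSer,Balkans,14,9
Slovenia,WSlv,Balkans,12,0
Hungary,WHun,Carpathians,14,0
Romania,WRom,Carpathians,18,2
Slovakia,WSlk,Carpathians,5,0
Portugal,WPor,Iberia,9,0
Spain,WSpa,Iberia,14,0
Italy,WIta,Italy,19,0
Sardinia,WSar,Sardinia,25,3
Austria,WAus,Central-West Europe,9,8
Belgium,WBel,Central-West Europe,6,0
France,WFra,Central-West Europe,25,1
Germany,WGer,Central-West Europe,16,1
Luxembourg,WLux,Central-West Europe,4,0
Netherlands,WNed,Central-West Europe,25,0
Estonia,WEst,Central-North-Eastern Europe,15,0
Finland,WFin,Central-North-Eastern Europe,3,0
Poland,WPol,Central-North-Eastern Europe,12,0
Russia,WRus,Central-North-Eastern Europe,4,0
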