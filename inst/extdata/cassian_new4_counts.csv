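sample_id,taxon_id,count
Costalaresc,Helenostylina convexa,230
Costalaresc,Dentineritaria neritina,18
Costalaresc,Domerionina stuorense,16
Costalaresc,Palaeonucula sp. 2,10
Costalaresc,Neritaria mandelslohi,10
Costalaresc,Plagioglypta undulata,9
Costalaresc,Ampezzopleura hybridopsis,7
Costalaresc,Atorcula anoptychopsis,5
Costalaresc,Ampezzopleura bandeli,4
Costalaresc,Spirostylus brevior,3
Costalaresc,Domerionina sp. 1,3
Picolbach,Domerionina stuorense,59
Picolbach,Caenogastropoda sp. 1,24
Picolbach,Plagioglypta undulata,24
Picolbach,Palaeonucula sp. 1,23
Picolbach,Domerionina sp. 1,22
Picolbach,Azyga dolomitensis,15
Picolbach,Domerionina pralongiana,15
Picolbach,Helenostylina convexa,11
Picolbach,Stuorilda cassiana,10
Picolbach,Neritaria mandelslohi,10
Rumerlo cliff,Camposcala biserta,50
Rumerlo cliff,Ruganeritaria subovata,48
Rumerlo cliff,Costactaeon n. sp.,35
Rumerlo cliff,Stuorilda cassiana,30
Rumerlo cliff,Zygopleura depressa,20
Rumerlo cliff,Tofanella cancellata,9
Rumerlo cliff,Teretrina cf. bolina,9
Rumerlo cliff,Prostylifer paludinaris,7
Rumerlo cliff,Coelostylina conica,6
Rumerlo cliff,Domerionina n. sp.,5
Rumerlo cliff,Palaeonucula sp. 1,5
Rumerlo cliff,Frederikella cancellata,5
Rumerlo ski slope,Camposcala biserta,7
Rumerlo ski slope,Zygopleura campoensis,5
Rumerlo ski slope,Costactaeon n. sp.,4
Rumerlo ski slope,Promathildia decorata,3
Rumerlo ski slope,Fedaiella elongata,3
Rumerlo ski slope,Kittliconcha? sp.,2
Rumerlo ski slope,Zygopleura hybridissima,2
Rumerlo ski slope,Ampezzopleura bandeli,2
Rumerlo ski slope,Neritaria plicatilis,2
Rumerlo ski slope,Popenella misurina,1
Rumerlo ski slope,Stuorilda tichyi,1
Rumerlo ski slope,Rinaldoconchus bieleri,1
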