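colony_id,name,state,region,latitude,longitude,area_ha,height_m
DMI,Deen Maar Island,Victoria,Bonney Upwelling,-38.4167,142.0000,150,40
SR,Seal Rocks,Victoria,Central Bass Strait,-38.5000,145.1667,8,10
Kan,Kanowna Island,Victoria,Central Bass Strait,-39.1667,146.3000,130,90
Ske,The Skerries,Victoria,East Australian Current,-37.7500,149.5167,8,10
Rag,Rag Island,Victoria,Central Bass Strait,-38.9667,146.7000,3,15
CB,Cape Bridgewater,Victoria,Bonney Upwelling,-38.3833,141.4000,1,0
MarR,Marengo Reef,Victoria,Bonney Upwelling,-38.7667,143.6700,1,0
RR,Reid Rocks,Tasmania,Western Tasmanian Shelf Upwelling,-40.2333,144.1500,10,8
WM,West Moncoeur,Tasmania,Central Bass Strait,-39.2333,146.5000,4,30
JR,Judgement Rocks,Tasmania,Central Bass Strait,-39.5000,147.1167,14,50
TI,Tenth Island,Tasmania,Central Bass Strait,-40.9500,146.9833,1,8
MR,Moriarty Rocks,Tasmania,East Australian Current,-40.5833,148.2667,4,7
WR,Wright Rocks,Tasmania,Central Bass Strait,-39.6000,147.5500,4,30
DR,Double Rocks,Tasmania,Central Bass Strait,-40.3333,147.9167,1,15
BR,Bull Rocks,Tasmania,Western Tasmanian Shelf Upwelling,-40.7333,147.2833,1,5
Sloop,Sloop Rocks,Tasmania,Western Tasmanian Shelf Upwelling,-42.3000,145.1667,2,15
IdP,Iles des Phoques,Tasmania,Sub-Antarctic surface waters,-42.4167,148.1500,8,7
Maat,Maatsuyker Island,Tasmania,Sub-Antarctic surface waters,-43.6333,146.2833,186,284
Wen,Wendar Island,Tasmania,Sub-Antarctic surface waters,-43.4000,145.9167,5.8,40
Nde,Needle Rocks,Tasmania,Sub-Antarctic surface waters,-43.6500,146.2500,10.5,42
Wal,Walker Island,Tasmania,Sub-Antarctic surface waters,-43.6167,146.2667,15,84
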