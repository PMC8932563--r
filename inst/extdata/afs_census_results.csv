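colony_id,site,region,pups_2007,se_2007,pups_2013,se_2013,pups_2017,se_2017,change_2007_2013,change_2013_2017
SR,Seal Rocks,Central Bass Strait,5660,83,4092,38,3865,41,-28,-6
Kan,Kanowna Is.,Central Bass Strait,3078,NA,3382,NA,3239,NA,+10,-4
JR,Judgement Rocks,Central Bass Strait,2387,75,1710,24,1752,103,-28,+2
Rag,Rag Is.,Central Bass Strait,277,NA,295,NA,351,NA,+7,+19
WR,Wright Rocks,Central Bass Strait,130,1,187,2,289,7,+44,+54
TI,Tenth Is.,Central Bass Strait,448,20,138,4,240,10,-69,+74
DR,Double Rocks,Central Bass Strait,51,NA,157,2,346,3,+207,+120
WM,West Moncoeur,Central Bass Strait,204,6,256,3,NA,NA,+25,Na
DMI,Deen Maar Is.,Bonney Upwelling,5574,73,2659,16,2866,24,-52,+8
CB,Cape Bridgewater,Bonney Upwelling,7,NA,120,NA,169,NA,+>1000,+41
MarR,Marengo Reef,Bonney Upwelling,NA,NA,NA,NA,5,NA,Na,Na
NC,North Casuarina,Kangaroo Island upwelling,28,NA,75,3.2,NA,NA,+168,Na
CG,Cape Gantheaume,Kangaroo Island upwelling,0,NA,1,NA,0,NA,Na,Na
WI,Williams Is.,Eyre Peninsula Upwelling,NA,NA,2,NA,NA,NA,Na,Na
RR,Reid Rocks,Western Tasmanian Shelf Upwelling,395,NA,1570,60,1568,9,+297,0
Sloop,Sloop Rocks,Western Tasmanian Shelf Upwelling,0,NA,16,NA,31,NA,Na,+94
BR,Bull Rocks,Western Tasmanian Shelf Upwelling,7,NA,21,NA,44,1.0,+200,+109
Bau,Baudin Rocks,Western Tasmanian Shelf Upwelling,NA,NA,6,NA,NA,NA,Na,Na
IdP,Illes des Phoques,Sub-Antarctic surface waters,0,NA,10,NA,31,0,Na,+210
Nde,Needles,Sub-Antarctic surface waters,NA,NA,0,NA,155,NA,Na,Na
Wal,Walker Is.,Sub-Antarctic surface waters,NA,NA,0,NA,96,NA,Na,Na
Wen,Wendar Is.,Sub-Antarctic surface waters,NA,NA,0,NA,45,NA,Na,Na
Maat,Maatsuyker Is.,Sub-Antarctic surface waters,1,NA,0,NA,76,NA,Na,Na
MR,Moriarty Rocks,East Australian Current,598,9,486,9,82,9,-19,-83
Ske,The Skerries,East Australian Current,2705,31,2254,33,1611,27,-17,-28
Mon,Montague Is.,East Australian Current,2,NA,19,0.3,NA,NA,+850,Na
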