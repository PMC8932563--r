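colony_id,colony,df,beta_year,intercept,z,p_value,ci_low,ci_high,dev_exp,theta
SR,Seal Rocks,6,0.00,1.15,0.41,0.69,-0.02,0.02,1.9,24.2
Kan,Kanowna Is.,10,0.01,-7.60,1.15,0.25,-0.01,0.02,10.7,67.1
JR,Judgement Rocks,9,-0.01,29.00,-2.00,0.05,-0.02,0.00,26.6,63.7
Rag,Rag Is.,4,0.11,-217.74,20.22,0.00,0.10,0.12,72.7,1200253.7
WR,Wright Rocks,9,0.25,-500.52,7.80,0.00,0.19,0.33,87.9,2.0
TI,Tenth Is.,8,-0.01,34.29,-1.03,0.30,-0.04,0.01,9.4,9.5
DR,Double Rocks,3,0.21,-420.79,16.95,0.00,0.19,0.24,97.9,536596.3
WM,West Moncoeur,9,0.00,6.94,-0.08,0.94,-0.02,0.02,0.1,24.8
DMI,Deen Maar Is.,4,-0.04,93.87,-3.40,0.00,-0.07,-0.02,67.6,28.8
CB,Cape Bridgewater,9,0.23,-452.30,8.23,0.00,0.17,0.29,87.6,6.6
NC,North Casuarina,3,0.22,-431.97,7.58,0.00,0.16,0.28,93.5,81458.3
RR,Reid Rocks,10,0.01,-20.79,0.60,0.55,-0.02,0.05,4.1,2.0
Sloop,Sloop Rocks,2,0.04,-84.45,2.16,0.03,0.01,0.09,64.9,3572.5
BR,Bull Rocks,5,0.17,-330.93,7.90,0.00,0.13,0.21,94.8,154751.3
IdP,Illes des Phoques,5,0.28,-562.33,5.83,0.00,0.20,0.39,94.3,49309.4
MR,Moriarty Rocks,10,-0.03,71.44,-1.80,0.07,-0.07,0.01,16.8,3.3
Ske,The Skerries,5,-0.01,23.98,-0.85,0.40,-0.03,0.01,9.7,38.7
Mon,Montague Is.,5,0.18,-361.16,4.00,0.00,0.10,0.28,82.7,10.0
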