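"survey_id","country_id","stratum","psu","weight","wealth_quintile","months_since_birth","place_code","attendant_code","stay_value","stay_unit","pnc_value","pnc_unit"
"SVY_A","ALPHA","S1","1",1.012,1,14,"11","2",,,24,"hrs"
"SVY_A","ALPHA","S1","1",1.682,2,16,"21","1",1,"day",3,"day"
"SVY_A","ALPHA","S1","1",1.047,3,7,"26","1",6,"hrs",3,"day"
"SVY_A","ALPHA","S1","1",1.498,4,20,"21","1",1,"day",2,"day"
"SVY_A","ALPHA","S1","2",1.059,5,20,"21","1",12,"hrs",50,"hrs"
"SVY_A","ALPHA","S1","2",0.682,1,3,"21","1",6,"hrs",2,"day"
"SVY_A","ALPHA","S1","2",1.746,2,20,"21","1",30,"hrs",,"none"
"SVY_A","ALPHA","S1","2",1.127,3,12,"11","2",,,50,"hrs"
"SVY_A","ALPHA","S2","1",0.623,4,0,"21","1",2,"day",2,"day"
"SVY_A","ALPHA","S2","1",0.764,5,30,"21","1",1,"day",2,"day"
"SVY_A","ALPHA","S2","1",0.771,1,2,"21","1",1,"day",50,"hrs"
"SVY_A","ALPHA","S2","1",1.51,2,20,"21","1",30,"hrs",,"none"
"SVY_A","ALPHA","S2","2",1.41,3,18,"21","1",1,"day",3,"day"
"SVY_A","ALPHA","S2","2",0.889,4,12,"22","1",48,"hrs",50,"hrs"
"SVY_A","ALPHA","S2","2",1.386,5,0,"22","1",6,"hrs",3,"day"
"SVY_A","ALPHA","S2","2",1.113,1,5,"21","1",6,"hrs",24,"hrs"
"SVY_A","BRAVO","S1","1",1.615,1,21,"11","1",,,,"none"
"SVY_A","BRAVO","S1","1",1.046,2,0,"22","1",48,"hrs",,"none"
"SVY_A","BRAVO","S1","1",1.802,3,4,"26","1",1,"day",,"none"
"SVY_A","BRAVO","S1","1",1.554,4,5,"99","1",12,"hrs",,"none"
"SVY_A","BRAVO","S1","2",0.697,5,3,"11","2",,,2,"day"
"SVY_A","BRAVO","S1","2",0.858,1,13,"11","2",,,3,"day"
"SVY_A","BRAVO","S1","2",0.776,2,21,"11","2",,,50,"hrs"
"SVY_A","BRAVO","S1","2",1.132,3,12,"22","1",12,"hrs",24,"hrs"
"SVY_A","BRAVO","S2","1",0.805,4,1,"22","1",2,"day",3,"day"
"SVY_A","BRAVO","S2","1",1.084,5,17,"22","1",6,"hrs",24,"hrs"
"SVY_A","BRAVO","S2","1",1.245,1,15,"21","1",1,"day",3,"day"
"SVY_A","BRAVO","S2","1",1.819,2,13,"11","2",,,,"none"
"SVY_A","BRAVO","S2","2",1.583,3,17,"22","1",48,"hrs",24,"hrs"
"SVY_A","BRAVO","S2","2",1.983,4,14,"21","1",48,"hrs",24,"hrs"
"SVY_A","BRAVO","S2","2",0.608,5,7,"11","1",,,3,"day"
"SVY_A","BRAVO","S2","2",0.714,1,16,"11","1",,,6,"hrs"
"SVY_B","CHARLIE","S1","1",0.962,1,20,"11","2",,,50,"hrs"
"SVY_B","CHARLIE","S1","1",1.291,2,15,"11","1",,,2,"day"
"SVY_B","CHARLIE","S1","1",0.941,3,5,"11","2",,,3,"day"
"SVY_B","CHARLIE","S1","1",1.332,4,14,"22","1",6,"hrs",24,"hrs"
"SVY_B","CHARLIE","S1","2",1.982,5,8,"11","2",,,,"none"
"SVY_B","CHARLIE","S1","2",0.547,1,8,"11","2",,,2,"day"
"SVY_B","CHARLIE","S1","2",0.57,2,21,"11","2",,,6,"hrs"
"SVY_B","CHARLIE","S1","2",1.453,3,8,"11","2",,,6,"hrs"
"SVY_B","CHARLIE","S2","1",1.845,4,2,"11","2",,,50,"hrs"
"SVY_B","CHARLIE","S2","1",1.9,5,17,"11","2",,,3,"day"
"SVY_B","CHARLIE","S2","1",0.572,1,21,"11","2",,,,"none"
"SVY_B","CHARLIE","S2","1",1.242,2,10,"11","2",,,,"none"
"SVY_B","CHARLIE","S2","2",1.622,3,16,"11","2",,,24,"hrs"
"SVY_B","CHARLIE","S2","2",0.829,4,2,"11","2",,,3,"day"
"SVY_B","CHARLIE","S2","2",0.896,5,4,"22","1",30,"hrs",50,"hrs"
"SVY_B","CHARLIE","S2","2",1.858,1,23,"11","2",,,50,"hrs"
"SVY_A","ALPHA","S1","1",-1,1,14,"11","2",,,24,"hrs"
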