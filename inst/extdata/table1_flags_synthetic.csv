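"sample_id","site","n_mapped_otus","tp","at5pe"
"S01","FL",25,50,1200
"S02","FL",25,50,1200
"S03","FL",10,50,300
"S04","FL",10,50,300
"S05","FL",10,50,1200
"S06","MA",25,95,300
"S07","MA",25,95,300
"S08","MA",25,95,300
"S09","MA",25,95,300
"S10","MA",25,95,300
"S11","MA",25,95,300
"S12","MA",25,95,300
"S13","MA",25,95,300
"S14","MA",25,95,300
"S15","MA",25,95,300
"S16","MA",25,95,300
"S17","MA",25,95,300
"S18","MA",25,50,300
"S19","MA",25,50,1200
"S20","MA",25,50,1200
"S21","MA",25,50,1200
"S22","MA",10,95,300
"S23","MA",10,95,300
"S24","MA",10,95,300
"S25","MA",10,50,300
"S26","MA",10,50,1200
"S27","MA",10,50,1200
"S28","MA",10,50,1200
"S29","MA",10,50,1200
"S30","MA",10,50,1200
"S31","MA",10,50,1200
"S32","MA",10,50,1200
"S33","MA",10,50,1200
"S34","NM",25,95,300
"S35","NM",25,95,300
"S36","NM",25,50,1200
"S37","NM",25,50,1200
"S38","NM",10,95,300
"S39","SC",25,95,300
"S40","SC",25,95,300
"S41","SC",10,50,1200
"S42","SC",10,50,1200
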