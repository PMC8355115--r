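"sample_id","site","n_mapped_otus","tp","at5pe"
"W01","WLOH",25,95,300
"W02","WLOH",25,95,300
"W03","WLOH",25,95,300
"W04","WLOH",25,95,300
"W05","WLOH",25,95,300
"W06","WLOH",25,50,300
"W07","WLOH",25,50,1200
"W08","WLOH",25,50,300
"W09","WLOH",25,50,1200
"W10","WLOH",25,50,300
"W11","WLOH",25,50,1200
"W12","WLOH",25,50,300
"W13","WLOH",10,95,300
"W14","WLOH",10,95,300
"W15","WLOH",10,95,300
"W16","WLOH",10,95,300
"W17","WLOH",10,95,300
"W18","WLOH",10,50,300
"W19","WLOH",10,50,1200
"W20","WLOH",10,50,300
"W21","WLOH",10,50,1200
"W22","WLOH",10,50,300
"W23","WLOH",10,50,1200
"W24","WLOH",10,50,300
"W25","WLOH",10,50,1200
"W26","WLOH",10,50,300
"W27","WLOH",10,50,1200
"W28","WLOH",10,50,300
"W29","WLOH",10,50,1200
"W30","WLOH",10,50,300
"W31","WLOH",10,50,1200
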