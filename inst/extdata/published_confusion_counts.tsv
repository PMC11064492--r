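model	tp_co	fn_co	fn_cf	tp_cf
knn	401	145	130	1976
svm_linear	369	177	104	2002
svm_rbf	343	206	163	1943
svm_polynomial	376	170	140	1966
svm_sigmoid	158	388	176	1930
xgboost	445	101	80	2026
random_forest	429	117	119	1987
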