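# toy 5-dimensional word-vector table: word v1 ... v5
chemo 1.371 0.3219 1.201 -0.0407 -2.0009
radiation -0.5647 -0.7838 1.0448 -1.5515 0.3338
taxol 0.3631 1.5757 -1.0032 1.1672 1.1713
surgery 0.6329 0.6429 1.8485 -0.2736 2.0595
mastectomy 0.4043 0.0898 -0.6668 -0.4678 -1.3769
tumor -0.1061 0.2766 0.1055 -1.2383 -1.1509
biopsy 1.5115 0.6793 -0.4223 -0.0078 -0.7058
scan -0.0947 0.0898 -0.1224 -0.8003 -1.0541
oncologist 2.0184 -2.9931 0.1882 -0.5335 -0.6457
diagnosis -0.0627 0.2849 0.1192 1.2877 -0.1854
pain 1.3049 -0.3672 -0.0251 -0.1755 -1.2012
hair 2.2866 0.1852 0.1081 -1.0718 2.037
swelling -1.3889 0.5818 -0.4854 0.1632 0.1078
fatigue -0.2788 1.3997 -0.5042 -0.3627 -0.0841
sore -0.1333 -0.7273 -1.6611 0.59 0.4956
numbness 0.636 1.3025 -0.3823 1.4324 0.0374
rash -0.2843 0.3358 -0.5127 -0.9927 -0.1321
nausea -2.6565 1.0385 2.7019 0.4547 1.4768
scared -2.4405 0.9207 -1.3621 0.0849 -0.217
anxiety 1.3201 0.7209 0.1373 0.8956 -1.2836
depressed -0.3066 -1.0431 -1.4936 -0.2298 0.3857
cry -1.7813 -0.0902 -1.4704 0.8366 -0.3515
fear -0.1719 0.6235 0.1247 -1.7451 -0.5218
stress 1.2147 -0.9535 -0.9966 1.6895 -1.0681
exercise 1.8952 -0.5428 -0.0018 0.8648 0.4284
diet -0.4305 0.581 -0.4283 -0.1508 -0.174
vitamins -0.2573 0.7682 -0.6137 -1.449 0.5157
sleep -1.7632 0.4638 -2.0247 0.643 -0.2344
nutrition 0.4601 -0.8858 -1.2247 0.4832 -0.6585
insurance -0.64 -1.0998 0.1795 -0.0064 1.2502
website 0.4555 1.5127 0.5676 0.1515 -0.2718
book 0.7048 0.2579 -0.4929 -0.5841 0.948
research 1.0351 0.0884 1e-04 0.3688 -1.2016
family -0.6089 -0.1209 1.1229 0.2947 -0.4661
husband 0.505 -1.1943 1.4399 -0.2793 -0.2694
friend -1.717 0.612 -1.0971 -1.3362 -0.391
help -0.7845 -0.2171 -0.1173 0.7007 1.3487
experience -0.8509 -0.1828 1.2015 0.5542 -0.0228
treatment -2.4142 0.9333 -0.4697 -0.8363 0.2442
normal 0.0361 0.8218 -0.0525 -1.5946 -0.9424
wondering 0.206 1.3921 -0.0861 0.205 -0.7292
question -0.3611 -0.4762 -0.8877 -0.3451 0.9981
advice 0.7582 0.6503 -0.4447 0.2526 1.2585
anyone -0.7267 1.3911 -0.0294 -1.294 1.2489
how -1.3683 -1.1108 -0.4139 -0.9592 -1.3806
what 0.4328 -0.8608 1.1134 1.0858 2.05
doctor -0.8114 -1.1317 -0.481 0.4038 1.0169
cancer 1.4441 -1.4592 -0.4332 0.5865 -0.0267
breast -0.4314 0.08 0.6969 1.8152 0.7036
feel 0.6556 0.6532 -1.0564 0.1288 -0.9714
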