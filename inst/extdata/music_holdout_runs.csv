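# Published per-experiment hold-out accuracies (%) for four-emotion
# recognition on a single-subject music-induced corpus: 10 repeated 80/20
# splits of 500 randomly drawn fused-feature samples, classified by an OvO
# RBF-SVM, a gain-ratio decision tree, an ELM, and the SVM-DT-ELM team
# strategy. Used as reference input for the mean +/- sd summary statistic.
experiment,svm,dt,elm,team
1,96,91,86,98
2,96,91,89,98
3,95,92,89,98
4,95,89,91,99
5,94,90,88,98
6,95,90,90,98
7,95,93,92,99
8,96,89,90,100
9,96,90,88,99
10,97,90,91,99
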