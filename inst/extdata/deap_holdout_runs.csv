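# Published per-experiment hold-out accuracies (%) for quadrant (HVHA/HVLA/
# LVLA/LVHA) recognition from peripheral channels of five subjects of a
# video-induced corpus: 10 repeated 300/100 splits per subject, classified
# by a decision tree, an ELM, an OvO RBF-SVM, and the SVM-DT-ELM team
# strategy ("team"). Used as reference input for the summary statistics.
subject,method,e1,e2,e3,e4,e5,e6,e7,e8,e9,e10
s01,dt,64,61,58,60,58,59,59,60,62,62
s01,elm,62,60,64,58,62,58,64,60,64,63
s01,svm,75,72,72,76,75,77,72,73,71,72
s01,team,80,80,80,81,80,82,79,79,76,78
s02,dt,55,51,53,53,50,56,51,57,52,55
s02,elm,58,54,59,52,53,56,53,57,57,55
s02,svm,68,66,71,63,63,64,64,66,63,63
s02,team,72,70,76,70,69,70,68,70,68,70
s03,dt,62,58,59,63,62,61,57,59,60,62
s03,elm,65,63,61,63,62,62,63,63,65,62
s03,svm,84,82,80,82,83,81,80,81,80,82
s03,team,88,88,87,89,86,86,87,86,87,86
s04,dt,58,62,60,57,61,58,59,58,63,58
s04,elm,48,51,49,47,53,50,47,52,53,51
s04,svm,63,66,65,64,65,60,61,60,62,61
s04,team,70,70,72,72,73,68,70,70,68,67
s05,dt,50,52,52,55,50,51,59,51,52,55
s05,elm,57,58,52,50,56,53,54,51,52,56
s05,svm,69,67,68,66,76,69,70,70,69,68
s05,team,75,73,78,73,82,75,75,74,75,75
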