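task,parameter,youden,youden_lo,youden_hi,sensitivity,sensitivity_lo,sensitivity_hi,specificity,specificity_lo,specificity_hi,consistent
lesion_vs_norm,SAI,0.735,0.612,0.882,0.832,0.623,0.966,0.903,0.737,1.0,TRUE
lesion_vs_norm,AmplAsymAvg,0.715,0.581,0.833,0.777,0.662,0.903,0.938,0.786,1.0,TRUE
lesion_vs_norm,AmplAsymAvg_2/3,0.633,0.482,0.788,0.764,0.5,0.911,0.869,0.667,1.0,TRUE
lesion_vs_norm,AmplAsymWeighted,0.595,0.395,0.779,0.827,0.697,0.952,0.921,0.765,1.0,FALSE
lesion_vs_norm,AbsPhaseDiffAvg,0.627,0.435,0.8,0.808,0.587,0.919,0.819,0.636,1.0,TRUE
lesion_vs_norm,AbsPhaseDiffWeighted,0.595,0.395,0.779,0.783,0.625,0.938,0.812,0.571,1.0,TRUE
malignant_vs_benign,SAI,0.545,0.379,0.705,0.733,0.54,0.913,0.812,0.621,0.955,TRUE
malignant_vs_benign,AmplAsymAvg,0.538,0.362,0.705,0.763,0.538,0.889,0.775,0.634,0.941,TRUE
malignant_vs_benign,AmplAsymAvg_2/3,0.440,0.259,0.606,0.624,0.375,0.825,0.816,0.629,0.974,TRUE
malignant_vs_benign,AmplAsymWeighted,0.503,0.334,0.667,0.725,0.442,0.895,0.778,0.605,0.976,TRUE
malignant_vs_benign,AbsPhaseDiffAvg,0.366,0.2,0.532,0.668,0.341,0.923,0.698,0.424,0.956,TRUE
malignant_vs_benign,AbsPhaseDiffWeighted,0.369,0.189,0.544,0.648,0.355,0.895,0.72,0.432,0.968,TRUE
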