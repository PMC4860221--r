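model,fold,pred1_act1,pred1_act2,pred2_act1,pred2_act2,accuracy,rmse
mlp,1,378,55,91,405,0.8428,0.3562
mlp,2,367,56,102,404,0.8299,0.3676
mlp,3,411,104,58,356,0.8256,0.3859
mlp,4,406,96,63,364,0.8288,0.3718
mlp,5,378,56,90,405,0.8428,0.3619
mlp,6,386,79,82,382,0.8267,0.3768
mlp,7,407,97,61,363,0.8297,0.3791
mlp,8,375,63,93,397,0.8319,0.3746
mlp,9,389,73,79,387,0.8362,0.3642
mlp,10,397,83,71,377,0.8341,0.3670
knn,1,432,38,37,422,0.9193,0.2841
knn,2,433,41,35,420,0.9182,0.2860
knn,3,432,34,37,426,0.9236,0.2764
knn,4,430,41,39,419,0.9139,0.2934
knn,5,426,32,43,428,0.9193,0.2841
knn,6,422,36,46,425,0.9117,0.2971
knn,7,433,33,35,427,0.9267,0.2707
knn,8,429,33,39,427,0.9224,0.2785
knn,9,424,35,44,425,0.9149,0.2917
knn,10,431,40,37,420,0.9170,0.2880
random_forest,1,445,40,24,420,0.9311,0.2584
random_forest,2,449,60,20,400,0.9139,0.2655
random_forest,3,440,52,29,408,0.9128,0.2692
random_forest,4,434,43,35,417,0.9160,0.2665
random_forest,5,428,53,40,408,0.8999,0.2821
random_forest,6,427,50,41,411,0.9020,0.2881
random_forest,7,446,65,22,395,0.9063,0.2773
random_forest,8,437,50,31,410,0.9127,0.2728
random_forest,9,441,60,27,400,0.9063,0.2788
random_forest,10,426,54,42,406,0.8966,0.2812
logistic_regression,1,406,67,63,393,0.8601,0.3352
logistic_regression,2,404,78,65,382,0.8461,0.3458
logistic_regression,3,386,62,83,398,0.8439,0.3511
logistic_regression,4,385,67,84,393,0.8375,0.3561
logistic_regression,5,410,87,58,374,0.8439,0.3512
logistic_regression,6,391,70,78,390,0.8407,0.3573
logistic_regression,7,386,62,82,398,0.8448,0.3551
logistic_regression,8,379,64,89,396,0.8351,0.3602
logistic_regression,9,393,71,75,389,0.8427,0.3546
logistic_regression,10,390,68,78,392,0.8427,0.3480
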