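participant_id,model,outcome,threshold,precision_pct,accuracy_pct,sensitivity_pct,specificity_pct,positive_days,total_days
1054,random_forest,headache,0.25,65.4,72.7,85.0,62.5,20,44
1054,random_forest,headache,0.50,71.4,75.0,75.0,75.0,20,44
1054,random_forest,headache,0.75,73.3,70.5,55.0,83.3,20,44
1041,elastic_net,migraine,0.25,36.4,46.2,100.0,22.2,12,39
1041,elastic_net,migraine,0.50,33.3,51.3,58.3,48.1,12,39
1041,elastic_net,migraine,0.75,0.0,66.7,0.0,96.3,12,39
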