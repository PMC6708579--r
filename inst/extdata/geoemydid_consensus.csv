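dataset,method,alignment,ta_dq,ta_cd,internal_nodes,resolution,n_tips
anterior_lobe,LAUP,GPA,0.952,0.784,8,0.182,46
anterior_lobe,LAUP,Dynamic,0.959,0.865,7,0.159,46
anterior_lobe,SCP,GPA,0.740,0.595,16,0.364,46
anterior_lobe,LP,GPA,0.953,0.811,8,0.182,46
anterior_lobe,ML,GPA,0.992,0.865,5,0.114,46
anterior_lobe,NJ,GPA,0.944,0.730,10,0.227,46
posterior_lobe,LAUP,GPA,0.945,0.730,8,0.182,46
posterior_lobe,LAUP,Dynamic,0.915,0.703,10,0.227,46
posterior_lobe,SCP,GPA,0.844,0.514,21,0.477,46
posterior_lobe,LP,GPA,0.981,0.797,8,0.182,46
posterior_lobe,ML,GPA,0.985,0.878,5,0.114,46
posterior_lobe,NJ,GPA,0.938,0.703,10,0.227,46
plastron,LAUP,GPA,0.874,0.689,13,0.295,46
plastron,LAUP,Dynamic,0.790,0.689,14,0.318,46
plastron,SCP,GPA,0.818,0.568,16,0.364,46
plastron,LP,GPA,0.946,0.743,12,0.273,46
plastron,ML,GPA,0.882,0.730,9,0.205,46
plastron,NJ,GPA,0.922,0.784,7,0.159,46
carapace,LAUP,GPA,0.858,0.609,21,0.500,44
carapace,LAUP,Dynamic,0.978,0.812,17,0.405,44
carapace,SCP,GPA,0.967,0.783,16,0.381,44
carapace,LP,GPA,0.922,0.667,18,0.429,44
carapace,ML,GPA,0.919,0.681,16,0.381,44
carapace,NJ,GPA,0.864,0.565,22,0.524,44
shell,LAUP,GPA,0.942,0.731,16,0.400,42
shell,LAUP,Dynamic,0.784,0.627,19,0.475,42
shell,SCP,GPA,0.918,0.657,15,0.375,42
shell,LP,GPA,0.932,0.687,18,0.450,42
shell,ML,GPA,0.944,0.761,12,0.300,42
shell,NJ,GPA,0.945,0.776,9,0.225,42
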