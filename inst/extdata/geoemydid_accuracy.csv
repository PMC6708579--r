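dataset,method,alignment,ta_dq,ta_cd,tree_score,ref_tree_score
anterior_lobe,LAUP,GPA,0.213,0.108,5.522,7.045
anterior_lobe,LAUP,Dynamic,0.225,0.162,5.269,6.586
anterior_lobe,SCP,GPA,0.202,0.135,0.070,0.116
anterior_lobe,LP,GPA,0.179,0.108,8.712,11.216
anterior_lobe,ML,GPA,0.195,0.135,8153.209,7833.224
anterior_lobe,NJ,GPA,0.194,0.162,,
posterior_lobe,LAUP,GPA,0.232,0.135,5.377,6.708
posterior_lobe,LAUP,Dynamic,0.222,0.122,5.032,6.285
posterior_lobe,SCP,GPA,0.227,0.122,0.067,0.110
posterior_lobe,LP,GPA,0.219,0.162,7.510,9.443
posterior_lobe,ML,GPA,0.247,0.162,6272.722,6055.839
posterior_lobe,NJ,GPA,0.278,0.176,,
plastron,LAUP,GPA,0.221,0.135,11.278,13.753
plastron,LAUP,Dynamic,0.212,0.162,10.649,12.872
plastron,SCP,GPA,0.203,0.108,0.151,0.226
plastron,LP,GPA,0.213,0.149,16.898,20.659
plastron,ML,GPA,0.225,0.149,14175.090,13753.905
plastron,NJ,GPA,0.247,0.162,,
carapace,LAUP,GPA,0.405,0.246,6.742,7.682
carapace,LAUP,Dynamic,0.360,0.319,5.995,7.151
carapace,SCP,GPA,0.324,0.290,0.032,0.043
carapace,LP,GPA,0.263,0.232,15.397,17.845
carapace,ML,GPA,0.317,0.246,54196.470,53287.233
carapace,NJ,GPA,0.445,0.261,,
shell,LAUP,GPA,0.309,0.269,18.285,20.198
shell,LAUP,Dynamic,0.319,0.269,16.340,18.856
shell,SCP,GPA,0.249,0.179,0.191,0.246
shell,LP,GPA,0.358,0.239,32.576,35.929
shell,ML,GPA,0.284,0.254,59202.235,58325.959
shell,NJ,GPA,0.283,0.239,,
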