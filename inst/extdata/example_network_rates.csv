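disease,network,measure,value_per_1000
diabetes,net1,incidence,4.1
diabetes,net2,incidence,3.7
diabetes,net3,incidence,4.7
diabetes,net4,incidence,5.4
diabetes,net5,incidence,4.8
copd,net1,incidence,2.2
copd,net2,incidence,2.6
copd,net3,incidence,3.0
copd,net4,incidence,3.9
copd,net5,incidence,4.4
heart_failure,net1,incidence,1.8
heart_failure,net2,incidence,2.4
heart_failure,net3,incidence,2.6
heart_failure,net4,incidence,4.8
heart_failure,net5,incidence,2.2
knee_oa,net1,incidence,2.4
knee_oa,net2,incidence,3.4
knee_oa,net3,incidence,3.5
knee_oa,net4,incidence,4.5
knee_oa,net5,incidence,3.2
diabetes,net1,prevalence,54
diabetes,net2,prevalence,48
diabetes,net3,prevalence,50
diabetes,net4,prevalence,61
diabetes,net5,prevalence,57
copd,net1,prevalence,26
copd,net2,prevalence,22
copd,net3,prevalence,25
copd,net4,prevalence,22
copd,net5,prevalence,33
heart_failure,net1,prevalence,11
heart_failure,net2,prevalence,13
heart_failure,net3,prevalence,11
heart_failure,net4,prevalence,18
heart_failure,net5,prevalence,8
knee_oa,net1,prevalence,12
knee_oa,net2,prevalence,39
knee_oa,net3,prevalence,10
knee_oa,net4,prevalence,20
knee_oa,net5,prevalence,28
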