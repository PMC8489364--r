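condition,peep_cmH2O,endpoint,value
healthy,5,pf_ratio,502
healthy,12,pf_ratio,532
healthy,17,pf_ratio,512
healthy,22,pf_ratio,513
healthy,27,pf_ratio,515
healthy,5,P_aw_insp,31
healthy,12,P_aw_insp,37
healthy,17,P_aw_insp,41
healthy,22,P_aw_insp,43
healthy,27,P_aw_insp,51
healthy,5,P_es_exp,12
healthy,12,P_es_exp,17
healthy,17,P_es_exp,21
healthy,22,P_es_exp,24
healthy,27,P_es_exp,27
healthy,5,P_es_insp,29
healthy,12,P_es_insp,34
healthy,17,P_es_insp,36
healthy,22,P_es_insp,38
healthy,27,P_es_insp,43
healthy,5,E_rs,103
healthy,12,E_rs,94
healthy,17,E_rs,85
healthy,22,E_rs,81
healthy,27,E_rs,92
healthy,5,E_W,67
healthy,12,E_W,66
healthy,17,E_W,53
healthy,22,E_W,55
healthy,27,E_W,60
healthy,5,E_L,35
healthy,12,E_L,35
healthy,17,E_L,30
healthy,22,E_L,27
healthy,27,E_L,31
healthy,5,cardiac_output,4.4
healthy,12,cardiac_output,3.9
healthy,17,cardiac_output,3.2
healthy,22,cardiac_output,2.9
healthy,27,cardiac_output,2.8
healthy,5,total_lung_volume_L,0.8
healthy,12,total_lung_volume_L,0.9
healthy,17,total_lung_volume_L,1
healthy,22,total_lung_volume_L,1.1
healthy,27,total_lung_volume_L,1.3
healthy,5,gas_volume_mL,378
healthy,12,gas_volume_mL,511
healthy,17,gas_volume_mL,620
healthy,22,gas_volume_mL,761
healthy,27,gas_volume_mL,903
healthy,5,tissue_mass_g,338
healthy,12,tissue_mass_g,355
healthy,17,tissue_mass_g,352
healthy,22,tissue_mass_g,353
healthy,27,tissue_mass_g,351
healthy,5,overdistended_pct,1
healthy,12,overdistended_pct,2
healthy,17,overdistended_pct,2
healthy,22,overdistended_pct,4
healthy,27,overdistended_pct,5
healthy,5,normally_aerated_pct,56
healthy,12,normally_aerated_pct,68
healthy,17,normally_aerated_pct,75
healthy,22,normally_aerated_pct,79
healthy,27,normally_aerated_pct,82
healthy,5,poorly_aerated_pct,32
healthy,12,poorly_aerated_pct,23
healthy,17,poorly_aerated_pct,18
healthy,22,poorly_aerated_pct,14
healthy,27,poorly_aerated_pct,9
healthy,5,atelectatic_pct,10
healthy,12,atelectatic_pct,5
healthy,17,atelectatic_pct,3
healthy,22,atelectatic_pct,3
healthy,27,atelectatic_pct,2
injured,5,pf_ratio,175
injured,12,pf_ratio,235
injured,17,pf_ratio,244
injured,22,pf_ratio,285
injured,27,pf_ratio,243
injured,5,P_aw_insp,38
injured,12,P_aw_insp,40
injured,17,P_aw_insp,44
injured,22,P_aw_insp,47
injured,27,P_aw_insp,57
injured,5,P_es_exp,30
injured,12,P_es_exp,34
injured,17,P_es_exp,38
injured,22,P_es_exp,40
injured,27,P_es_exp,44
injured,5,P_es_insp,16
injured,12,P_es_insp,20
injured,17,P_es_insp,23
injured,22,P_es_insp,26
injured,27,P_es_insp,29
injured,5,E_rs,115
injured,12,E_rs,109
injured,17,E_rs,101
injured,22,E_rs,89
injured,27,E_rs,105
injured,5,E_W,62
injured,12,E_W,61
injured,17,E_W,54
injured,22,E_W,53
injured,27,E_W,57
injured,5,E_L,53
injured,12,E_L,42
injured,17,E_L,38
injured,22,E_L,35
injured,27,E_L,48
injured,5,cardiac_output,4.2
injured,12,cardiac_output,3.3
injured,17,cardiac_output,3.2
injured,22,cardiac_output,3.1
injured,27,cardiac_output,3.3
injured,5,total_lung_volume_L,1
injured,12,total_lung_volume_L,1.2
injured,17,total_lung_volume_L,1.3
injured,22,total_lung_volume_L,1.5
injured,27,total_lung_volume_L,1.7
injured,5,gas_volume_mL,428
injured,12,gas_volume_mL,569
injured,17,gas_volume_mL,744
injured,22,gas_volume_mL,885
injured,27,gas_volume_mL,1024
injured,5,tissue_mass_g,446
injured,12,tissue_mass_g,489
injured,17,tissue_mass_g,526
injured,22,tissue_mass_g,546
injured,27,tissue_mass_g,548
injured,5,overdistended_pct,2
injured,12,overdistended_pct,2
injured,17,overdistended_pct,3
injured,22,overdistended_pct,3
injured,27,overdistended_pct,5
injured,5,normally_aerated_pct,44
injured,12,normally_aerated_pct,55
injured,17,normally_aerated_pct,60
injured,22,normally_aerated_pct,63
injured,27,normally_aerated_pct,69
injured,5,poorly_aerated_pct,26
injured,12,poorly_aerated_pct,25
injured,17,poorly_aerated_pct,24
injured,22,poorly_aerated_pct,24
injured,27,poorly_aerated_pct,19
injured,5,atelectatic_pct,26
injured,12,atelectatic_pct,18
injured,17,atelectatic_pct,11
injured,22,atelectatic_pct,6
injured,27,atelectatic_pct,3
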