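stream,visit_form,drg_weight,expected_sek
primary,physician,,1800
primary,other_hcp,,720
primary,group,,720
primary,team,,2700
primary,group_team,,2700
primary,home,,3600
primary,indirect,,600
primary,physician,,1800
specialised_outpatient,,1.5,40500
specialised_outpatient,,0,0
specialised_outpatient,,,3600
specialised_outpatient,indirect,,1200
specialised_outpatient,other_hcp,,1440
inpatient,,1.234,33318
inpatient,,2,54000
polyclinical,,0.5,13500
polyclinical,,0.037,999
specialised_outpatient,,0.456,12312
inpatient,,0.001,27
primary,indirect,,600
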