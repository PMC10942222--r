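# phase_duration MHT 100
# phase_duration DGB 80
# parkland_grade 2
# cvs_score 1
# intraop_events cholecystic_vascular_injury,liver_thermal_injury
video_id,surgeon_id,phase,label,hand,start_s,end_s
W02.F03,W02,MHT,hook,unattributed,0,20
W02.F03,W02,MHT,hook,unattributed,25,45
W02.F03,W02,MHT,hook,unattributed,50,70
W02.F03,W02,DGB,hook,unattributed,0,30
W02.F03,W02,DGB,hook,unattributed,40,70
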