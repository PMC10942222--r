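# phase_duration MHT 50
# phase_duration DGB 50
# parkland_grade 1
# cvs_score 0
# intraop_events cholecystic_vascular_injury
video_id,surgeon_id,phase,label,hand,start_s,end_s
W02.F04,W02,MHT,blunt_dissection,unattributed,5,25
W02.F04,W02,DGB,grasp,right,10,30
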