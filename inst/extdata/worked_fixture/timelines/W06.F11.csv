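# phase_duration MHT 160
# phase_duration DGB 120
# parkland_grade 2
# cvs_score 1
# intraop_events liver_thermal_injury,cholecystic_vascular_injury
video_id,surgeon_id,phase,label,hand,start_s,end_s
W06.F11,W06,MHT,inefficient_grasp,left,0,30
W06.F11,W06,MHT,inefficient_hook,unattributed,5,25
W06.F11,W06,MHT,push,right,35,60
W06.F11,W06,MHT,inefficient_grasp,left,40,75
W06.F11,W06,MHT,inefficient_hook,unattributed,80,105
W06.F11,W06,MHT,push,right,110,130
W06.F11,W06,DGB,inefficient_grasp,left,0,35
W06.F11,W06,DGB,push,right,10,30
W06.F11,W06,DGB,inefficient_hook,unattributed,40,70
W06.F11,W06,DGB,push,right,75,95
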