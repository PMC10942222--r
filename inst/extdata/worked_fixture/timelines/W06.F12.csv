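# phase_duration MHT 140
# phase_duration DGB 100
# parkland_grade 1
# cvs_score 2
# intraop_events liver_thermal_injury
video_id,surgeon_id,phase,label,hand,start_s,end_s
W06.F12,W06,MHT,grasp,left,0,35
W06.F12,W06,MHT,inefficient_hook,unattributed,8,30
W06.F12,W06,MHT,push,right,40,65
W06.F12,W06,MHT,inefficient_grasp,left,45,80
W06.F12,W06,MHT,hook,unattributed,85,105
W06.F12,W06,DGB,inefficient_grasp,left,0,30
W06.F12,W06,DGB,hook,unattributed,10,35
W06.F12,W06,DGB,irrigate,unattributed,40,60
W06.F12,W06,DGB,suction,unattributed,60,80
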