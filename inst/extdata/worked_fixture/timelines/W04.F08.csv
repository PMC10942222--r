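# phase_duration MHT 90
# phase_duration DGB 70
# parkland_grade 2
# cvs_score 1
# intraop_events liver_thermal_injury
video_id,surgeon_id,phase,label,hand,start_s,end_s
W04.F08,W04,MHT,grasp,right,0,20
W04.F08,W04,MHT,inefficient_hook,unattributed,5,25
W04.F08,W04,MHT,hook,unattributed,30,50
W04.F08,W04,MHT,push,left,55,70
W04.F08,W04,DGB,grasp,right,0,25
W04.F08,W04,DGB,hook,unattributed,10,30
W04.F08,W04,DGB,coagulate,unattributed,35,55
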