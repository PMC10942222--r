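# phase_duration MHT 150
# phase_duration DGB 100
# parkland_grade 1
# cvs_score 4
# intraop_events liver_thermal_injury
video_id,surgeon_id,phase,label,hand,start_s,end_s
W03.F05,W03,MHT,grasp,left,0,30
W03.F05,W03,MHT,hook,unattributed,5,15
W03.F05,W03,MHT,hook,unattributed,18,28
W03.F05,W03,MHT,grasp,left,35,60
W03.F05,W03,MHT,push,right,40,55
W03.F05,W03,MHT,spread,right,60,75
W03.F05,W03,MHT,pull,left,70,85
W03.F05,W03,MHT,retract,right,80,95
W03.F05,W03,DGB,grasp,left,0,40
W03.F05,W03,DGB,hook,unattributed,5,20
W03.F05,W03,DGB,push,right,25,35
W03.F05,W03,DGB,coagulate,unattributed,45,60
W03.F05,W03,DGB,irrigate,unattributed,65,80
W03.F05,W03,DGB,suction,unattributed,80,95
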