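# phase_duration MHT 120
# phase_duration DGB 90
# parkland_grade 1
# cvs_score 3
# intraop_events liver_thermal_injury
video_id,surgeon_id,phase,label,hand,start_s,end_s
W01.F01,W01,MHT,grasp,left,0,8
W01.F01,W01,MHT,hook,unattributed,2,6
W01.F01,W01,MHT,hook,unattributed,8,14
W01.F01,W01,MHT,inefficient_grasp,left,10,18
W01.F01,W01,MHT,blunt_dissection,unattributed,20,30
W01.F01,W01,MHT,push,right,32,40
W01.F01,W01,MHT,clip,unattributed,45,50
W01.F01,W01,MHT,cut,unattributed,55,60
W01.F01,W01,DGB,grasp,left,0,10
W01.F01,W01,DGB,hook,unattributed,4,12
W01.F01,W01,DGB,coagulate,unattributed,15,25
W01.F01,W01,DGB,suction,unattributed,30,38
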