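# phase_duration MHT 200
# phase_duration DGB 150
# parkland_grade 1
# cvs_score 2
# intraop_events liver_thermal_injury,gallbladder_broken
video_id,surgeon_id,phase,label,hand,start_s,end_s
W04.F07,W04,MHT,grasp,left,0,25
W04.F07,W04,MHT,inefficient_hook,unattributed,5,20
W04.F07,W04,MHT,inefficient_hook,unattributed,25,45
W04.F07,W04,MHT,inefficient_grasp,left,30,55
W04.F07,W04,MHT,push,right,50,70
W04.F07,W04,MHT,push,right,75,95
W04.F07,W04,MHT,hook,unattributed,100,115
W04.F07,W04,MHT,blunt_dissection,unattributed,120,150
W04.F07,W04,DGB,inefficient_grasp,left,0,30
W04.F07,W04,DGB,inefficient_hook,unattributed,10,35
W04.F07,W04,DGB,push,right,40,60
W04.F07,W04,DGB,hook,unattributed,65,90
W04.F07,W04,DGB,suction,unattributed,95,120
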