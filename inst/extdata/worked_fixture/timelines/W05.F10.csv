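# phase_duration MHT 70
# phase_duration DGB 55
# parkland_grade 1
# cvs_score 3
video_id,surgeon_id,phase,label,hand,start_s,end_s
W05.F10,W05,MHT,grasp,left,0,18
W05.F10,W05,MHT,hook,unattributed,4,14
W05.F10,W05,MHT,spread,right,20,30
W05.F10,W05,MHT,clip,unattributed,34,40
W05.F10,W05,DGB,grasp,left,0,20
W05.F10,W05,DGB,hook,unattributed,5,15
W05.F10,W05,DGB,cut,unattributed,20,28
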