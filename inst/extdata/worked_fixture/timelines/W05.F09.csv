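# phase_duration MHT 110
# phase_duration DGB 85
# parkland_grade 1
# cvs_score 5
video_id,surgeon_id,phase,label,hand,start_s,end_s
W05.F09,W05,MHT,grasp,left,0,20
W05.F09,W05,MHT,hook,unattributed,2,12
W05.F09,W05,MHT,hook,unattributed,14,24
W05.F09,W05,MHT,cut,unattributed,28,34
W05.F09,W05,MHT,clip,unattributed,38,44
W05.F09,W05,MHT,hook,unattributed,48,60
W05.F09,W05,DGB,grasp,left,0,25
W05.F09,W05,DGB,hook,unattributed,3,18
W05.F09,W05,DGB,blunt_dissection,unattributed,22,40
W05.F09,W05,DGB,coagulate,unattributed,44,56
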