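# phase_duration MHT 80
# phase_duration DGB 60
# parkland_grade 1
# cvs_score 2
video_id,surgeon_id,phase,label,hand,start_s,end_s
W03.F06,W03,MHT,grasp,left,0,15
W03.F06,W03,MHT,hook,unattributed,20,30
W03.F06,W03,MHT,pull,left,35,50
W03.F06,W03,DGB,grasp,left,0,20
W03.F06,W03,DGB,hook,unattributed,25,40
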