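# phase_duration MHT 60
# phase_duration DGB 40
# parkland_grade 1
# cvs_score 2
video_id,surgeon_id,phase,label,hand,start_s,end_s
W01.F02,W01,MHT,hook,unattributed,0,10
W01.F02,W01,MHT,hook,unattributed,10,20
W01.F02,W01,MHT,blunt_dissection,unattributed,20,30
W01.F02,W01,DGB,hook,unattributed,0,15
W01.F02,W01,DGB,coagulate,unattributed,15,30
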