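video_id,rater_id,dp,bd,eff,th
W01.F01,R1,4,4,5,4
W01.F01,R2,5,4,4,4
W01.F02,R1,5,5,4,5
W01.F02,R2,4,5,5,4
W02.F03,R1,2,2,3,2
W02.F03,R2,2,3,2,2
W02.F04,R1,3,2,2,3
W02.F04,R2,2,2,3,2
W03.F05,R1,5,5,5,5
W03.F05,R2,5,4,5,5
W03.F06,R1,4,5,4,5
W03.F06,R2,5,4,5,4
W04.F07,R1,2,3,2,2
W04.F07,R2,3,2,2,3
W04.F08,R1,3,3,4,3
W04.F08,R2,3,4,3,3
W05.F09,R1,4,4,4,5
W05.F09,R2,4,5,4,4
W05.F10,R1,4,3,4,4
W05.F10,R2,3,4,4,4
W06.F11,R1,1,2,1,2
W06.F11,R2,2,1,2,1
W06.F12,R1,3,2,3,2
W06.F12,R2,2,3,2,3
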