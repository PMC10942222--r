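video_id,surgeon_id,count.grasp.L,count.grasp.R,count.inefficient_grasp.L,count.inefficient_grasp.R,count.pull.L,count.pull.R,count.push.L,count.push.R,count.retract.L,count.retract.R,count.spread.L,count.spread.R,count.blunt_dissection,count.clip,count.coagulate,count.cut,count.hook,count.inefficient_hook,count.irrigate,count.suction,dur.grasp.L,dur.grasp.R,dur.inefficient_grasp.L,dur.inefficient_grasp.R,dur.pull.L,dur.pull.R,dur.push.L,dur.push.R,dur.retract.L,dur.retract.R,dur.spread.L,dur.spread.R,dur.blunt_dissection,dur.clip,dur.coagulate,dur.cut,dur.hook,dur.inefficient_hook,dur.irrigate,dur.suction,int.all.mean,int.all.max,int.all.min,int.all.sd,int.left.mean,int.left.max,int.left.min,int.left.sd,int.right.mean,int.right.max,int.right.min,int.right.sd,shift.all,shift.left,shift.right,de.count_D,de.count_E,de.dur_D,de.dur_E,de.count_ratio,de.dur_ratio,de.shift,manip_time
W01.F01,W01,2,0,1,0,0,0,0,1,0,0,0,0,1,1,1,1,3,0,0,1,18,0,8,0,0,0,0,8,0,0,0,0,10,5,10,5,18,0,0,8,2.4,5,0,2.06559111797729,2,2,2,0,0,0,0,0,2.57142857142857,0.285714285714286,0,7,5,48,42,1.4,1.14285714285714,2,3.5
W01.F02,W01,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,3,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,10,0,15,0,35,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1.2,0,0,5,0,60,0,5,60,0,1.66666666666667
W02.F03,W02,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,5,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,120,0,0,0,6.66666666666667,10,5,2.88675134594813,0,0,0,0,0,0,0,0,0,0,0,5,0,120,0,5,120,0,3
W02.F04,W02,0,1,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,20,0,0,0,0,0,0,0,0,0,0,20,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,1,20,20,1,1,0,1.66666666666667
W03.F05,W03,3,0,0,0,1,0,0,2,0,1,0,1,0,0,1,0,3,0,1,1,95,0,0,0,15,0,0,25,0,15,0,15,0,0,15,0,35,0,15,15,2.91666666666667,10,0,3.4498572653829,7.5,10,5,3.53553390593274,5,5,5,0,2.64,0.24,0.48,5,9,65,180,0.555555555555556,0.361111111111111,1.92,4.16666666666667
W03.F06,W03,2,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,2,0,0,0,35,0,0,0,15,0,0,0,0,0,0,0,0,0,0,0,25,0,0,0,5,5,5,0,20,20,20,0,0,0,0,0,1.28571428571429,0.428571428571429,0,2,3,25,50,0.666666666666667,0.5,1.28571428571429,2.33333333333333
W04.F07,W04,1,0,2,0,0,0,0,3,0,0,0,0,1,0,0,0,2,3,0,1,25,0,55,0,0,0,0,60,0,0,0,0,30,0,0,0,40,60,0,25,3.18181818181818,5,0,2.52262489554756,5,5,5,0,5,5,5,0,1.54285714285714,0.171428571428571,0,6,7,130,165,0.857142857142857,0.787878787878788,1.2,5.83333333333333
W04.F08,W04,0,2,0,0,0,0,1,0,0,0,0,0,0,0,1,0,2,1,0,0,0,45,0,0,0,0,15,0,0,0,0,0,0,0,20,0,40,20,0,0,3,5,0,2.73861278752583,0,0,0,0,0,0,0,0,1.875,0,0,4,3,80,60,1.33333333333333,1.33333333333333,1.125,2.66666666666667
W05.F09,W05,2,0,0,0,0,0,0,0,0,0,0,0,1,1,1,1,4,0,0,0,45,0,0,0,0,0,0,0,0,0,0,0,18,6,12,6,47,0,0,0,2.75,4,0,1.83225076262581,0,0,0,0,0,0,0,0,2.15384615384615,0,0,8,2,89,45,4,1.97777777777778,0.615384615384615,3.25
W05.F10,W05,2,0,0,0,0,0,0,0,0,0,0,1,0,1,0,1,2,0,0,0,38,0,0,0,0,0,0,0,0,0,0,10,0,6,0,8,20,0,0,0,3,6,0,2.82842712474619,0,0,0,0,0,0,0,0,2.4,0,0,5,2,44,38,2.5,1.15789473684211,0.96,2.08333333333333
W06.F11,W06,0,0,3,0,0,0,0,4,0,0,0,0,0,0,0,0,0,3,0,0,0,0,100,0,0,0,0,85,0,0,0,0,0,0,0,0,0,75,0,0,4.375,10,0,4.1726148019814,10,10,10,0,47.5,50,45,3.53553390593274,1.71428571428571,0,0,3,7,75,185,0.428571428571429,0.405405405405405,1.28571428571429,4.66666666666667
W06.F12,W06,1,0,2,0,0,0,0,1,0,0,0,0,0,0,0,0,2,1,1,1,35,0,65,0,0,0,0,25,0,0,0,0,0,0,0,0,45,22,20,20,2.85714285714286,10,0,3.93397896234722,10,10,10,0,0,0,0,0,1.75,0.25,0,3,6,67,165,0.5,0.406060606060606,1.25,4
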