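segment
TRAV1
TRAV2
TRAV3
TRAV4
TRAV5
TRAV6
TRAV7
TRAV8
TRAV9
TRAV10
TRAV11
TRAV12
TRAV13
TRAV14
TRAV15
TRAV16
TRAV17
TRAV18
TRAV19
TRAV20
TRAV21
TRAV22
TRAV23
TRAV24
TRAV25
TRAV26
TRAV27
TRAV28
TRAV29
TRAV30
TRAV31
TRAV32
TRAV33
TRAV34
TRAV35
TRAV36
TRAV37
TRAV38
TRAV39
TRAV40
TRAV41
TRAV42
TRAV43
TRAV44
TRAV45
TRAJ1
TRAJ2
TRAJ3
TRAJ4
TRAJ5
TRAJ6
TRAJ7
TRAJ8
TRAJ9
TRAJ10
TRAJ11
TRAJ12
TRAJ13
TRAJ14
TRAJ15
TRAJ16
TRAJ17
TRAJ18
TRAJ19
TRAJ20
TRAJ21
TRAJ22
TRAJ23
TRAJ24
TRAJ25
TRAJ26
TRAJ27
TRAJ28
TRAJ29
TRAJ30
TRAJ31
TRAJ32
TRAJ33
TRAJ34
TRAJ35
TRAJ36
TRAJ37
TRAJ38
TRAJ39
TRAJ40
TRAJ41
TRAJ42
TRAJ43
TRAJ44
TRAJ45
TRAJ46
TRAJ47
TRAJ48
TRAJ49
TRAJ50
TRAJ51
TRAJ52
TRAJ53
TRAJ54
TRAJ55
TRAJ56
TRBV1
TRBV2
TRBV3
TRBV4
TRBV5
TRBV6
TRBV7
TRBV8
TRBV9
TRBV10
TRBV11
TRBV12
TRBV13
TRBV14
TRBV15
TRBV16
TRBV17
TRBV18
TRBV19
TRBV20
TRBV21
TRBV22
TRBV23
TRBV24
TRBV25
TRBV26
TRBV27
TRBV28
TRBV29
TRBV30
TRBD1
TRBD2
TRBJ1
TRBJ2
TRBJ3
TRBJ4
TRBJ5
TRBJ6
TRBJ7
TRBJ8
TRBJ9
TRBJ10
TRBJ11
TRBJ12
TRBJ13
TRDV1
TRDV2
TRDV3
TRDD1
TRDD2
TRDD3
TRDJ1
TRDJ2
TRDJ3
TRDJ4
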