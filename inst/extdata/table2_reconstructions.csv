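section;subgroup;measure;a1;a3;a6;a2;a4;a5
Axons;Total;total_length;1019,68;977,40;1059,31;1345,96;1069,19;1360,67
Axons;Excitatory;total_length;358,50;358,38;434,99;419,27;379,19;497,70
Axons;Inhibitory;total_length;133,31;96,28;90,02;116,48;89,45;83,05
Axons;Unknown;total_length;155,17;54,21;112,14;146,52;220,50;187,23
Axons;non-connecting neurites;total_length;372,69;468,52;422,16;663,70;380,06;592,70
Dendrites;Total;total_length;165,63;162,64;186,42;197,55;215,38;153,75
Boutons;Total;count;235;236;199;205;210;205
Boutons;Total;complete;142;157;114;101;95;86
Boutons;Total;incomplete;93;79;85;104;115;119
Boutons;Total;total_surface_area_complete;254,79;248,69;175,47;148,72;176,84;150,96
Boutons;Total;mean_surface_area;1,79;1,58;1,54;1,47;1,86;1,76
Boutons;Total;sd_surface_area;1,18;0,94;1,04;1,04;1,19;1,21
Boutons;Total;total_volume_complete;23,55;21,36;15,12;13,91;16,62;13,34
Boutons;Total;mean_volume;0,17;0,14;0,13;0,13;0,17;0,16
Boutons;Total;sd_volume;0,17;0,12;0,14;0,12;0,17;0,13
Boutons;Excitatory;count;148;112;146;133;110;133
Boutons;Excitatory;complete;85;84;83;61;53;63
Boutons;Excitatory;incomplete;148;112;146;72;57;70
Boutons;Excitatory;total_surface_area_complete;162,86;145,71;137,69;87,95;120,38;118,95
Boutons;Excitatory;mean_surface_area;1,92;1,73;1,66;1,44;2,27;1,89
Boutons;Excitatory;sd_surface_area;1,15;0,93;1,15;0,86;1,28;1,17
Boutons;Excitatory;total_volume_complete;14,88;12,89;12,41;8,73;12,51;11,39
Boutons;Excitatory;mean_volume;0,18;0,15;0,15;0,13;0,24;0,18
Boutons;Excitatory;sd_volume;0,14;0,12;0,16;0,11;0,20;0,16
Boutons;Inhibitory;count;38;30;30;34;26;20
Boutons;Inhibitory;complete;27;25;16;18;13;7
Boutons;Inhibitory;incomplete;38;30;30;16;13;14
Boutons;Inhibitory;total_surface_area_complete;61,49;43,26;22,10;42,84;23,67;17,87
Boutons;Inhibitory;mean_surface_area;2,28;1,73;1,38;2,38;1,82;2,55
Boutons;Inhibitory;sd_surface_area;1,42;0,89;0,57;1,46;0,94;1,82
Boutons;Inhibitory;total_volume_complete;6,76;3,99;1,70;4,13;1,95;1,14
Boutons;Inhibitory;mean_volume;0,25;0,16;0,11;0,23;0,15;0,19
Boutons;Inhibitory;sd_volume;0,30;0,13;0,07;0,19;0,10;0,11
Boutons;Unknown;count;49;95;23;38;74;52
Boutons;Unknown;complete;30;48;15;22;29;16
Boutons;Unknown;incomplete;49;95;23;16;45;36
Boutons;Unknown;total_surface_area_complete;30,44;59,72;15,68;17,94;32,79;14,14
Boutons;Unknown;mean_surface_area;1,01;1,24;1,05;0,82;1,13;0,88
Boutons;Unknown;sd_surface_area;0,54;0,90;0,46;0,42;0,65;0,44
Boutons;Unknown;total_volume_complete;1,91;4,49;1,01;1,05;2,17;0,80
Boutons;Unknown;mean_volume;0,06;0,09;0,07;0,05;0,07;0,05
Boutons;Unknown;sd_volume;0,05;0,11;0,04;0,03;0,06;0,03
Spines;Total;count;124;152;180;158;128;171
Spines;Total;complete;74;108;122;105;85;107
Spines;Total;incomplete;49;44;58;53;41;64
Spines;Total;total_surface_area_complete;65,47;98,98;89,52;82,52;92,98;78,35
Spines;Total;mean_surface_area;0,88;0,92;0,73;0,79;1,09;0,73
Spines;Total;sd_surface_area;0,70;0,72;0,56;0,66;0,79;0,67
Spines;Total;total_volume_complete;5,15;7,68;6,48;6,17;7,89;5,74
Spines;Total;mean_volume;0,07;0,07;0,05;0,06;0,09;0,05
Spines;Total;sd_volume;0,08;0,08;0,06;0,07;0,09;0,07
Spines;Total;total_length;90,96;139,31;135,94;122,16;95,62;127,45
Spines;Total;mean_length;1,60;1,33;1,39;1,44;1,47;1,45
Spines;Total;sd_length;0,86;0,54;0,74;0,69;0,55;0,61
Synapses;Total;count;189;167;211;212;185;171
Synapses;Total;complete;159;129;146;163;135;126
Synapses;Total;incomplete;30;38;65;49;50;45
Synapses;Total;total_surface_area_complete;23,39;25,00;17,02;24,56;22,79;20,11
Synapses;Total;mean_surface_area;0,15;0,19;0,12;0,15;0,17;0,16
Synapses;Total;sd_surface_area;0,13;0,15;0,10;0,17;0,14;0,15
Synapses;Excitatory;count;131;109;165;138;122;128
Synapses;Excitatory;complete;104;91;119;108;91;94
Synapses;Excitatory;incomplete;27;18;46;30;31;34
Synapses;Excitatory;total_surface_area_complete;15,73;18,76;14,26;17,67;17,60;16,71
Synapses;Excitatory;mean_surface_area;0,15;0,21;0,12;0,16;0,19;0,18
Synapses;Excitatory;sd_surface_area;0,14;0,15;0,10;0,15;0,16;0,17
Synapses;Inhibitory;count;34;25;30;29;32;23
Synapses;Inhibitory;complete;33;21;16;23;22;20
Synapses;Inhibitory;incomplete;1;4;14;6;10;3
Synapses;Inhibitory;total_surface_area_complete;5,59;3,98;1,85;1,78;3,11;2,66
Synapses;Inhibitory;mean_surface_area;0,17;0,19;0,12;0,08;0,14;0,13
Synapses;Inhibitory;sd_surface_area;0,12;0,11;0,09;0,06;0,09;0,11
Synapses;Unknown;count;24;33;16;45;31;20
Synapses;Unknown;complete;22;17;11;32;22;12
Synapses;Unknown;incomplete;2;16;5;13;9;8
Synapses;Unknown;total_surface_area_complete;2,07;2,26;0,91;5,10;2,08;0,74
Synapses;Unknown;mean_surface_area;0,09;0,13;0,08;0,16;0,09;0,06
Synapses;Unknown;sd_surface_area;0,08;0,18;0,07;0,24;0,06;0,04
Mitochondria;Total;count;187;181;202;219;210;183
Mitochondria;Axonal;count;130;130;146;149;149;137
Mitochondria;Dendritic;count;43;41;39;54;53;41
Mitochondria;Undefined;count;14;10;17;15;8;5
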