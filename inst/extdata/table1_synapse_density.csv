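animal;age;total_vol;n_synapses;total_density;asym_spine_single;asym_spine_msb;asym_shaft_single;asym_shaft_msb;sym_spine;sym_shaft;unknown
1;4 months;849,7224;1190;1,400;0,920;0,080;0,221;0,020;0,073;0,072;0,014
2;24 months;1416,69;1627;1,148;0,805;0,132;0,078;0,001;0,030;0,059;0,021
3;4 months;1520,7;2158;1,419;0,882;0,172;0,116;0,022;0,095;0,074;0,015
4;24 months;915,84;1080;1,179;0,850;0,080;0,142;0,008;0,016;0,066;0,016
5;24 months;662,592;790;1,192;0,838;0,168;0,103;0,003;0,009;0,071;0,002
6;4 months;705,6;989;1,402;0,959;0,152;0,113;0,027;0,045;0,094;0,011
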