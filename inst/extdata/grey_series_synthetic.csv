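"rel_exposure","mean_pixel","sd_pixel"
0.02,0.0962231171379215,0.0130653382885057
0.0270221559467796,0.125381597970682,0.0142420895877575
0.0365098456006039,0.159399607575449,0.0148622259582093
0.0493287370706183,0.203423411905888,0.0153861766500549
0.0666484412889969,0.255723877987084,0.0144546275995511
0.090049228706053,0.317169079351549,0.0143894213129395
0.12166621504911,0.385708237673132,0.0125910016732096
0.164384171825573,0.457849177868281,0.0115789019340781
0.222100736312643,0.527758409221512,0.0089055080732202
0.300082036626741,0.597377616302344,0.00789824558280507
0.405443179527752,0.668023536882288,0.0072632744142448
0.547797441237855,0.748822019568694,0.00758577775661677
0.740133394218809,0.859086210664966,0.00950484459447103
1,1.02262300825325,0.00807367965345132
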