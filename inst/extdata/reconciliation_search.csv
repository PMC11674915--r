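"se_ratio","head_hidden_units","bias","bn_variant","params","delta"
2,"",TRUE,"stem_only",1571715,-78305
4,"",TRUE,"stem_only",1569651,-80369
8,"",TRUE,"stem_only",1568619,-81401
16,"",TRUE,"stem_only",1568103,-81917
2,"256",TRUE,"stem_only",1637507,-12513
4,"256",TRUE,"stem_only",1635443,-14577
8,"256",TRUE,"stem_only",1634411,-15609
16,"256",TRUE,"stem_only",1633895,-16125
2,"128",TRUE,"stem_only",1604227,-45793
4,"128",TRUE,"stem_only",1602163,-47857
8,"128",TRUE,"stem_only",1601131,-48889
16,"128",TRUE,"stem_only",1600615,-49405
2,"512",TRUE,"stem_only",1704067,54047
4,"512",TRUE,"stem_only",1702003,51983
8,"512",TRUE,"stem_only",1700971,50951
16,"512",TRUE,"stem_only",1700455,50435
2,"",TRUE,"post_mim",1571971,-78049
4,"",TRUE,"post_mim",1569907,-80113
8,"",TRUE,"post_mim",1568875,-81145
16,"",TRUE,"post_mim",1568359,-81661
2,"256",TRUE,"post_mim",1637763,-12257
4,"256",TRUE,"post_mim",1635699,-14321
8,"256",TRUE,"post_mim",1634667,-15353
16,"256",TRUE,"post_mim",1634151,-15869
2,"128",TRUE,"post_mim",1604483,-45537
4,"128",TRUE,"post_mim",1602419,-47601
8,"128",TRUE,"post_mim",1601387,-48633
16,"128",TRUE,"post_mim",1600871,-49149
2,"512",TRUE,"post_mim",1704323,54303
4,"512",TRUE,"post_mim",1702259,52239
8,"512",TRUE,"post_mim",1701227,51207
16,"512",TRUE,"post_mim",1700711,50691
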