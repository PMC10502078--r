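food,rsid
dark_bread,rs1514175
dark_bread,rs543874
dark_bread,rs2867125
dark_bread,rs13107325
dark_bread,rs206936
dark_bread,rs7127684
dark_bread,rs7138803
dark_bread,rs1421085
dark_bread,rs571312
dark_bread,rs3810291
biscuits_cookies,rs543874
biscuits_cookies,rs11676272
biscuits_cookies,rs3817334
biscuits_cookies,rs7138803
biscuits_cookies,rs10134820
biscuits_cookies,rs2241423
biscuits_cookies,rs571312
sugary_juice_drink,rs2815752
sugary_juice_drink,rs1514175
sugary_juice_drink,rs543874
sugary_juice_drink,rs2867125
sugary_juice_drink,rs10938397
sugary_juice_drink,rs7138803
sugary_juice_drink,rs1421085
sweets_chocolate,rs2815752
sweets_chocolate,rs543874
sweets_chocolate,rs2867125
sweets_chocolate,rs11676272
sweets_chocolate,rs10938397
sweets_chocolate,rs2112347
sweets_chocolate,rs10134820
sweets_chocolate,rs1421085
sweets_chocolate,rs571312
sweets_chocolate,rs2287019
pizza,rs2815752
pizza,rs543874
pizza,rs2867125
pizza,rs11676272
pizza,rs887912
pizza,rs10938397
pizza,rs2112347
pizza,rs7127684
pizza,rs7138803
pizza,rs1421085
pizza,rs3810291
hamburger_hotdog,rs2815752
hamburger_hotdog,rs543874
hamburger_hotdog,rs2867125
hamburger_hotdog,rs11676272
hamburger_hotdog,rs10938397
hamburger_hotdog,rs10134820
hamburger_hotdog,rs1421085
milk_sourmilk,rs1514175
milk_sourmilk,rs543874
milk_sourmilk,rs11676272
milk_sourmilk,rs10938397
milk_sourmilk,rs206936
milk_sourmilk,rs2030323
milk_sourmilk,rs3817334
milk_sourmilk,rs7138803
milk_sourmilk,rs2241423
milk_sourmilk,rs12444979
milk_sourmilk,rs1421085
milk_sourmilk,rs571312
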