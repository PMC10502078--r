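food,scheme,p_continuous,p_dichotomized
dark_bread,unweighted,0.099,NA
dark_bread,speliotes,0.200,NA
dark_bread,finhit,0.240,NA
dark_bread,ratio,0.813,NA
sweet_pastry,unweighted,0.972,NA
sweet_pastry,speliotes,0.772,NA
sweet_pastry,finhit,0.541,NA
sweet_pastry,ratio,0.273,NA
biscuits_cookies,unweighted,0.411,NA
biscuits_cookies,speliotes,0.277,NA
biscuits_cookies,finhit,0.149,0.112
biscuits_cookies,ratio,0.449,NA
ice_cream,unweighted,0.311,NA
ice_cream,speliotes,0.389,NA
ice_cream,finhit,0.233,NA
ice_cream,ratio,0.263,NA
sugary_juice_drink,unweighted,0.190,NA
sugary_juice_drink,speliotes,0.131,NA
sugary_juice_drink,finhit,0.621,NA
sugary_juice_drink,ratio,0.451,NA
sugary_soft_drink,unweighted,0.669,NA
sugary_soft_drink,speliotes,0.691,NA
sugary_soft_drink,finhit,0.558,NA
sugary_soft_drink,ratio,0.342,NA
sweets_chocolate,unweighted,0.080,NA
sweets_chocolate,speliotes,0.060,NA
sweets_chocolate,finhit,0.575,NA
sweets_chocolate,ratio,0.386,NA
pizza,unweighted,0.017,NA
pizza,speliotes,0.078,NA
pizza,finhit,0.058,NA
pizza,ratio,0.309,NA
hamburger_hotdog,unweighted,0.756,NA
hamburger_hotdog,speliotes,0.878,NA
hamburger_hotdog,finhit,0.203,NA
hamburger_hotdog,ratio,0.153,0.079
milk_sourmilk,unweighted,0.567,NA
milk_sourmilk,speliotes,0.210,NA
milk_sourmilk,finhit,0.017,NA
milk_sourmilk,ratio,0.040,NA
cooked_vegetables,unweighted,0.276,NA
cooked_vegetables,speliotes,0.612,NA
cooked_vegetables,finhit,0.152,0.186
cooked_vegetables,ratio,0.165,NA
fresh_vegetables,unweighted,0.637,NA
fresh_vegetables,speliotes,0.770,NA
fresh_vegetables,finhit,0.733,NA
fresh_vegetables,ratio,0.637,NA
fruit_berries,unweighted,0.447,NA
fruit_berries,speliotes,0.367,NA
fruit_berries,finhit,0.612,NA
fruit_berries,ratio,0.501,NA
juice,unweighted,0.434,NA
juice,speliotes,0.393,NA
juice,finhit,0.987,NA
juice,ratio,0.171,NA
salty_snacks,unweighted,0.669,NA
salty_snacks,speliotes,0.659,NA
salty_snacks,finhit,0.963,NA
salty_snacks,ratio,0.562,NA
water,unweighted,0.771,NA
water,speliotes,0.744,NA
water,finhit,0.978,NA
water,ratio,0.637,NA
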