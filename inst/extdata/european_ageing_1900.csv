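country,final_year,pct65_initial,pct65_final,change_actual,change_both_fixed,change_fertility_fixed,change_mortality_fixed,nonvital_pct,fertility_pct,mortality_pct
Denmark,2016,6.7,18.8,12.1,-1.7,-0.6,8.4,-13.8,82.5,17.5
England and Wales,2016,4.7,18.0,13.3,0.9,3.8,7.0,6.4,62.8,37.2
Finland,2015,5.3,19.9,14.7,0.4,0.8,12.0,2.4,89.1,10.9
France,2015,8.5,18.6,10.2,0.5,5.2,3.7,5.3,42.5,57.5
Iceland,2016,6.6,13.9,7.3,-1.3,1.7,2.4,-18.1,54.1,45.9
Italy,2014,6.3,21.4,15.1,-1.5,-0.5,9.2,-10.1,79.0,21.0
Netherlands,2016,6.0,18.2,12.2,-0.8,0.1,8.9,-6.7,83.8,16.2
Norway,2014,7.8,15.9,8.1,-2.8,-2.1,5.6,-35.0,85.2,14.8
Scotland,2016,4.9,18.5,13.6,0.7,3.2,7.8,5.0,67.6,32.4
Sweden,2016,8.3,19.8,11.5,-2.4,-1.3,8.1,-21.0,83.9,16.1
Switzerland,2016,5.8,18.0,12.2,-1.9,1.1,4.6,-15.3,62.4,37.6
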